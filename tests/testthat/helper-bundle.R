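# Shared fixtures: the default synthetic bundle (seed fixed a priori) and
# the pipeline run over it, each built once per test session.

.fixture_env <- new.env(parent = emptyenv())

default_bundle <- function() {
  if (is.null(.fixture_env$bundle)) {
    dir <- file.path(tempdir(), "lrrfam-default-bundle")
    .fixture_env$bundle <- simulate_genome(sim_config(seed = 101), dir)
  }
  .fixture_env$bundle
}

default_pipeline <- function() {
  if (is.null(.fixture_env$pipeline)) {
    out <- file.path(tempdir(), "lrrfam-default-pipeline")
    .fixture_env$pipeline <-
      suppressMessages(run_pipeline(default_bundle(), out, verbose = FALSE))
    .fixture_env$pipeline_dir <- out
  }
  .fixture_env$pipeline
}

default_pipeline_dir <- function() {
  default_pipeline()
  .fixture_env$pipeline_dir
}

# Small handcrafted GFF3 annotation used across io/structure tests.
write_tiny_gff <- function(path, primary_flag = TRUE) {
  flag <- if (primary_flag) ";primary=true" else ""
  lines <- c(
    "##gff-version 3",
    "##sequence-region chr1 1 50000",
    "chr1\ttest\tgene\t1001\t3000\t.\t+\t.\tID=gA",
    paste0("chr1\ttest\tmRNA\t1001\t3000\t.\t+\t.\tID=gA.1;Parent=gA", flag),
    "chr1\ttest\texon\t1001\t1600\t.\t+\t.\tID=gA.1.e1;Parent=gA.1",
    "chr1\ttest\texon\t2001\t3000\t.\t+\t.\tID=gA.1.e2;Parent=gA.1",
    "chr1\ttest\tCDS\t1001\t1600\t.\t+\t0\tID=gA.1.c;Parent=gA.1",
    "chr1\ttest\tCDS\t2001\t3000\t.\t+\t0\tID=gA.1.c;Parent=gA.1",
    "chr1\ttest\tmRNA\t1001\t1600\t.\t+\t.\tID=gA.2;Parent=gA",
    "chr1\ttest\texon\t1001\t1600\t.\t+\t.\tID=gA.2.e1;Parent=gA.2",
    "chr1\ttest\tCDS\t1001\t1300\t.\t+\t0\tID=gA.2.c;Parent=gA.2",
    "chr1\ttest\tgene\t10001\t12000\t.\t-\t.\tID=gB",
    "chr1\ttest\tmRNA\t10001\t12000\t.\t-\t.\tID=gB.1;Parent=gB",
    "chr1\ttest\texon\t10001\t12000\t.\t-\t.\tID=gB.1.e1;Parent=gB.1",
    "chr1\ttest\tCDS\t10001\t12000\t.\t-\t0\tID=gB.1.c;Parent=gB.1")
  writeLines(lines, path)
  path
}
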