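test_that("replicate means and tau match hand values", {
  v <- matrix(c(10, 12, 0, 0, 2, 4,
                5, 5, 5, 5, 5, 5), nrow = 2, byrow = TRUE,
              dimnames = list(c("g1", "g2"), NULL))
  em <- expression_matrix(v, c("root", "root", "leaf", "leaf", "stem", "stem"),
                          rep(1:2, 3))
  cm <- replicate_means(em)
  expect_identical(colnames(cm), c("root", "leaf", "stem"))
  expect_equal(unname(cm["g1", ]), c(11, 0, 3))
  # tau of (11, 0, 3): (0 + 1 + 8/11) / 2
  expect_equal(lrrfam:::tau_score(cm["g1", ]), (1 + 8 / 11) / 2)
  expect_equal(lrrfam:::tau_score(cm["g2", ]), 0)
  expect_true(is.na(lrrfam:::tau_score(c(0, 0, 0))))
})

test_that("specificity calls distinguish specific, high, and none", {
  cm <- rbind(spec1 = c(100, 2, 1, 0, 0, 0, 0, 0),
              spec2 = c(80, 90, 1, 1, 1, 1, 1, 1),   # two-condition specific
              high = c(50, 10, 12, 11, 10, 10, 10, 10),
              flat = c(5, 5, 6, 5, 5, 5, 5, 5),
              zero = c(0, 0, 0, 0, 0, 0, 0, 0))
  colnames(cm) <- letters[1:8]
  calls <- specificity_calls(cm, tau_min = 0.8, fold_min = 2)
  get <- function(g, col) calls[[col]][calls$gene_id == g]
  expect_identical(get("spec1", "mode"), "specific")
  expect_identical(get("spec1", "called_conditions"), "a")
  expect_identical(get("spec2", "mode"), "specific")
  expect_identical(get("spec2", "called_conditions"), "a,b")
  expect_identical(get("high", "mode"), "high")
  expect_identical(get("high", "called_conditions"), "a")
  expect_identical(get("flat", "mode"), "none")
  expect_identical(get("zero", "mode"), "none")
  expect_true(is.na(get("zero", "tau")))
})

test_that("peak calls break ties by earliest time then genotype order", {
  conds <- c("A17:0", "A17:12", "skl:0", "skl:12")
  cm <- rbind(p1 = c(1, 8, 1, 8),     # tie at t=12: A17 first in columns
              p2 = c(4, 2, 4, 2),     # tie at t=0 incl. baseline; fold 1
              p3 = c(0, 0, 0, 5),     # zero baseline, nonzero peak
              p4 = c(0, 0, 0, 0))
  colnames(cm) <- conds
  pc <- peak_time_calls(cm, baseline = "A17:0", fold_min = 2)
  get <- function(g, col) pc[[col]][pc$gene_id == g]
  expect_identical(get("p1", "peak_condition"), "A17:12")
  expect_identical(get("p2", "peak_condition"), "A17:0")
  expect_false(get("p2", "called"))
  expect_identical(get("p3", "fold_over_baseline"), Inf)
  expect_true(get("p3", "called"))
  expect_false(get("p4", "called"))
  # explicit genotype preference flips the t=12 tie
  pc2 <- peak_time_calls(cm, baseline = "A17:0", fold_min = 2,
                         genotype_order = c("skl", "A17"))
  expect_identical(pc2$peak_condition[pc2$gene_id == "p1"], "skl:12")
  expect_error(peak_time_calls(cm, baseline = "nope"), "baseline")
})

test_that("heatmap order is deterministic and guards degenerate input", {
  cm <- rbind(a = c(1, 2, 30), b = c(1.1, 2.2, 29), c = c(50, 1, 1),
              d = c(49, 2, 2))
  o1 <- heatmap_order(cm)
  o2 <- heatmap_order(cm)
  expect_identical(o1, o2)
  expect_setequal(o1, rownames(cm))
  # similar rows end adjacent
  expect_equal(abs(match("a", o1) - match("b", o1)), 1L)
  expect_identical(heatmap_order(cm[1:2, ]), c("a", "b"))
  const <- matrix(3, 3, 4, dimnames = list(c("x", "y", "z"), NULL))
  expect_identical(heatmap_order(const), c("x", "y", "z"))
})

test_that("2^-ddCt recovers known fold changes from a noise-free table", {
  # target: dCt = 5 at calibrator, 5 - 3 = 2 at treated -> rel = 8
  ct <- rbind(
    data.frame(gene_id = "ref", sample_id = rep(c("cal", "trt"), each = 3),
               replicate = rep(1:3, 2), ct = 20),
    data.frame(gene_id = "tgt", sample_id = rep(c("cal", "trt"), each = 3),
               replicate = rep(1:3, 2), ct = rep(c(25, 22), each = 3)))
  res <- delta_delta_ct(ct, reference_gene = "ref", calibrator_sample = "cal")
  expect_equal(res$rel_expr[res$sample_id == "cal"], 1)
  expect_equal(res$rel_expr[res$sample_id == "trt"], 8)
  expect_equal(res$rel_sd, c(0, 0))
  expect_identical(res$n_reps, c(3L, 3L))
  expect_error(delta_delta_ct(ct, "ghost", "cal"), "reference gene")
  expect_error(delta_delta_ct(ct, "ref", "ghost"), "calibrator")
})
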