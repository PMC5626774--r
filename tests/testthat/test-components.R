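test_that("structural scores match the closed form 1 - v/v_max", {
  s <- structural_scores(data.frame(drug = c("A", "B", "C"),
                                    violations = c(0L, 8L, 16L)))
  expect_equal(s, c(A = 1.0, B = 0.5, C = 0.0))
  # no violations anywhere: no penalty to normalize
  expect_equal(structural_scores(c(a = 0, b = 0)), c(a = 1, b = 1))
  expect_error(structural_scores(data.frame(drug = character(),
                                            violations = integer())),
               "empty")
})

test_that("functional scores are mean-then-max normalized, empty lists give 0", {
  f <- functional_scores(list(A = c(0.4, 0.6), B = c(1, 1), C = numeric()))
  expect_equal(f, c(A = 0.5, B = 1.0, C = 0.0))
  expect_equal(functional_scores(list(only = 0.3))[["only"]], 1.0)
  # all-zero means stay zero, no division attempted
  expect_equal(functional_scores(list(a = numeric(), b = 0)),
               c(a = 0, b = 0))
  expect_error(functional_scores(list(a = 1.5)), "\\[0, 1\\]")
})

test_that("raw side-effect burden is the class-weighted count sum", {
  expect_equal(side_effect_raw(rep(0L, 8)), 0)
  expect_equal(side_effect_raw(c(2, 0, 0, 0, 0, 0, 0, 1)), 10)
  expect_equal(side_effect_raw(rep(1L, 8)), 36)
  # linearity in counts
  set.seed(9)
  for (i in 1:20) {
    a <- rpois(8, 3); b <- rpois(8, 3)
    expect_equal(side_effect_raw(a + b),
                 side_effect_raw(a) + side_effect_raw(b))
  }
})

se_profiles <- function(counts_list, unknown) {
  m <- do.call(rbind, counts_list)
  df <- data.frame(drug = sprintf("d%d", seq_along(counts_list)))
  for (i in 1:8) df[[paste0("c", i)]] <- m[, i]
  df$unknown <- unknown
  df
}

test_that("side-effect scores: 1 - S/S_max for known, exactly 0 for unknown", {
  prof <- se_profiles(list(rep(0, 8), c(2, 0, 0, 0, 0, 0, 0, 1), rep(1, 8)),
                      c(FALSE, FALSE, TRUE))
  s <- side_effect_scores(prof)
  expect_equal(s[["d1"]], 1.0)      # known, zero burden
  expect_equal(s[["d2"]], 0.0)      # heaviest known burden
  expect_equal(s[["d3"]], 0.0)      # unknown pinned to worst
  # all unknown: all zero, no division
  all_unk <- se_profiles(list(rep(0, 8), rep(2, 8)), c(TRUE, TRUE))
  expect_equal(unname(side_effect_scores(all_unk)), c(0, 0))
  # known burden-free batch scores all 1
  none <- se_profiles(list(rep(0, 8), rep(0, 8)), c(FALSE, FALSE))
  expect_equal(unname(side_effect_scores(none)), c(1, 1))
})

test_that("component scores hold [0,1] bounds, extremes and anti-monotonicity (1000+ cases)", {
  set.seed(77)
  for (rep in 1:350) {
    n <- sample(2:8, 1)
    v <- rpois(n, sample(1:10, 1))
    sv <- structural_scores(structure(as.numeric(v),
                                      names = sprintf("d%d", 1:n)))
    expect_true(all(sv >= 0 & sv <= 1))
    if (max(v) > 0) expect_equal(min(sv[v == max(v)]), 0)
    # anti-monotone: sort by violations, scores reverse-sorted
    expect_true(all(diff(sv[order(v)]) <= 1e-12))

    ev <- lapply(1:n, function(i) runif(sample(0:5, 1)))
    names(ev) <- sprintf("d%d", 1:n)
    fv <- functional_scores(ev)
    expect_true(all(fv >= 0 & fv <= 1))
    means <- vapply(ev, function(x) if (length(x)) mean(x) else 0, 1)
    if (max(means) > 0) expect_equal(max(fv), 1)
    expect_true(all(diff(fv[order(means)]) >= -1e-12))

    counts <- lapply(1:n, function(i) rpois(8, 2))
    unk <- runif(n) < 0.2
    prof <- se_profiles(counts, unk)
    ss <- side_effect_scores(prof)
    expect_true(all(ss >= 0 & ss <= 1))
    raw <- vapply(counts, side_effect_raw, 1)
    known <- !unk
    if (any(known)) {
      expect_true(all(diff(ss[which(known)[order(raw[known])]]) <= 1e-12))
    }
  }
})

test_that("normalization is batch-relative: a heavier newcomer rescales the others", {
  base <- structural_scores(c(a = 1, b = 2))
  wider <- structural_scores(c(a = 1, b = 2, z = 10))
  expect_equal(base[["a"]], 0.5)
  expect_equal(wider[["a"]], 0.9)   # same count, different batch, new score
  expect_gt(wider[["a"]], base[["a"]])
  # same effect for side effects
  p1 <- se_profiles(list(c(1, rep(0, 7)), c(2, rep(0, 7))), c(FALSE, FALSE))
  p2 <- rbind(p1, se_profiles(list(rep(5, 8)), FALSE))
  p2$drug <- c("d1", "d2", "d3")
  expect_gt(side_effect_scores(p2)[["d2"]], side_effect_scores(p1)[["d2"]])
})

test_that("assemble_components joins maps, applies only configured defaults", {
  maps <- component_maps()
  inhib <- golden_inhibition()$ipf_vs_normal
  cm <- assemble_components(inhib, maps$struct, maps$func, maps$side)
  lyc <- cm[cm$drug == "lycorine", ]
  expect_equal(unlist(lyc[, c("inhib", "struct", "func", "side")]),
               c(inhib = 0.915, struct = 1.000, func = 0.668, side = 0.000))
  # missing side entry: explicit default-unknown policy gives 0
  cm2 <- assemble_components(c(x = 0.5), c(x = 1), c(x = 0.2),
                             side = c(other = 1), universe = "x",
                             defaults = list(side = 0))
  expect_equal(cm2$side, 0)
  # missing inhibition is always an error
  expect_error(
    assemble_components(c(x = 0.5), c(x = 1, y = 1), c(x = 0, y = 0),
                        c(x = 0, y = 0), universe = c("x", "y")),
    "inhibition")
  expect_error(
    assemble_components(c(x = 0.5), c(other = 1), c(x = 0), c(x = 0),
                        universe = "x"),
    "struct")
})
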