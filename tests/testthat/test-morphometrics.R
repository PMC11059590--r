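test_that("areas and fractions follow forced pixel arithmetic", {
  # toy mask: 36 tuft px (incl. 10 mesangial) at 0.25 um/px
  g <- toy_glomerulus()
  m <- glomerulus_morphometrics(g)
  expect_equal(m$glomerular_area_um2, 36 * 0.25^2)
  expect_equal(m$mesangial_area_um2, 10 * 0.25^2)
  expect_equal(m$mesangial_area_fraction, 10 / 36)
  expect_equal(m$mesangial_area_fraction,
               m$mesangial_area_um2 / m$glomerular_area_um2)
})

test_that("disc area matches the analytic value within 2%", {
  g <- generate_glomerulus(glomerulus_spec("NOA", 80, 0), seed = 1)
  m <- glomerulus_morphometrics(g)
  expect_lt(abs(m$glomerular_area_um2 - pi * (80 * 0.25)^2) /
              (pi * (80 * 0.25)^2), 0.02)
})

test_that("cell counts, ratios and densities are consistent", {
  cells <- data.frame(
    cell_type = rep(c("mesangial", "endothelial", "podocyte"), c(10, 5, 5)),
    row = rep(3:8, length.out = 20),
    col = rep(3:8, each = 4)[1:20],
    stringsAsFactors = FALSE
  )
  g <- toy_glomerulus(cells = cells)
  m <- glomerulus_morphometrics(g)
  expect_identical(c(m$n_mesangial, m$n_endothelial, m$n_podocyte),
                   c(10L, 5L, 5L))
  expect_equal(c(m$ratio_mesangial, m$ratio_endothelial, m$ratio_podocyte),
               c(0.5, 0.25, 0.25))
  expect_equal(m$ratio_mesangial + m$ratio_endothelial + m$ratio_podocyte, 1)
  expect_equal(m$density_mesangial, 10 / m$glomerular_area_um2)
  expect_equal(m$mesangial_area_per_cell, m$mesangial_area_um2 / 10)
})

test_that("undefined per-cell quantities are NA when counts are zero", {
  g <- toy_glomerulus(cells = data.frame(cell_type = character(0),
                                         row = integer(0), col = integer(0)))
  m <- glomerulus_morphometrics(g)
  expect_true(is.na(m$mesangial_area_per_cell))
  expect_true(is.na(m$ratio_mesangial))
})

test_that("morphometrics are invariant to translation and background padding", {
  g <- generate_glomerulus(glomerulus_spec("NOA", 30, 0.2), seed = 8)
  m1 <- glomerulus_morphometrics(g)
  pad <- matrix(0L, nrow(g$mask) + 20, ncol(g$mask) + 20)
  pad[7 + seq_len(nrow(g$mask)), 13 + seq_len(ncol(g$mask))] <- g$mask
  cells2 <- transform(g$cells, row = row + 7, col = col + 13)
  m2 <- glomerulus_morphometrics(
    labeled_glomerulus(pad, cells2, g$lesion_type, g$pixel_size_um))
  m1$lesion_type <- m2$lesion_type <- NULL
  expect_equal(m1, m2)
})

test_that("midsection rule is >= 50 total intrinsic cells", {
  expect_true(is_midsection(c(20, 20, 10)))
  expect_false(is_midsection(c(20, 20, 9)))
  expect_true(is_midsection(c(50, 0, 0)))
  df <- glom_row(n_mes = 20, n_end = 20, n_pod = 9)
  expect_false(is_midsection(df))
})

test_that("mild mesangial expansion cutoff is strict at 0.2596", {
  expect_true(flag_mild_mesangial_expansion(0.20))
  expect_false(flag_mild_mesangial_expansion(0.2596))
  expect_false(flag_mild_mesangial_expansion(0.40))
  expect_error(flag_mild_mesangial_expansion(1.2), class = "glomRPS_bad_input")
})

test_that("patient_aggregate computes percents over all glomeruli", {
  rows <- do.call(rbind, c(
    lapply(1:4, function(i) glom_row("GS", glom_id = paste0("gs", i))),
    lapply(1:6, function(i) glom_row("NOA", glom_id = paste0("noa", i)))
  ))
  pf <- patient_aggregate(rows)
  expect_equal(pf$percent_GS, 40)
  expect_equal(pf$percent_NOA, 60)
  expect_equal(pf$percent_GS + pf$percent_SS + pf$percent_C + pf$percent_KW +
                 pf$percent_NOA, 100, tolerance = 1e-6)
  expect_false(pf$has_KW)
  expect_true(patient_aggregate(rbind(rows, glom_row("KW")))$has_KW)
})

test_that("midsection means cover only midsection KW/NOA glomeruli", {
  rows <- rbind(
    glom_row("NOA", mf = 0.2),
    glom_row("NOA", mf = 0.4),
    glom_row("NOA", mf = 0.9, n_mes = 5, n_end = 5, n_pod = 5),  # off midsection
    glom_row("GS", mf = 0.8)                                      # wrong type
  )
  pf <- patient_aggregate(rows)
  expect_equal(pf$ms_mesangial_area_fraction, 0.3)
  expect_identical(pf$n_midsection, 2L)
  # no midsection KW/NOA at all -> explicit missing
  pf2 <- patient_aggregate(glom_row("GS"))
  expect_true(is.na(pf2$ms_mesangial_area_fraction))
  expect_error(patient_aggregate(list()), class = "glomRPS_bad_input")
})

test_that("percents recover planted type frequencies on a large patient", {
  probs <- c(GS = 0.3, SS = 0.05, C = 0.01, KW = 0.16, NOA = 0.48)
  set.seed(77)
  types <- sample(names(probs), 1000, replace = TRUE, prob = probs)
  rows <- do.call(rbind, lapply(seq_along(types), function(i) {
    glom_row(types[i], glom_id = paste0("g", i))
  }))
  pf <- patient_aggregate(rows)
  for (ty in names(probs)) {
    ci <- qbinom(c(0.005, 0.995), 1000, probs[[ty]]) / 10 # percent scale
    expect_gte(pf[[paste0("percent_", ty)]], ci[1])
    expect_lte(pf[[paste0("percent_", ty)]], ci[2])
  }
})

test_that("compare_groups matches brute-force U and separates cleanly", {
  expect_equal(compare_groups(list(c(1, 2, 3), c(10, 11, 12)))$statistic, 0)
  set.seed(5)
  x <- runif(8); y <- runif(6)
  expect_equal(compare_groups(list(x, y))$statistic, u_bruteforce(x, y))
  expect_error(compare_groups(list(1:3)), class = "glomRPS_bad_input")
  expect_error(compare_groups(list(1:3, numeric(0))), class = "glomRPS_bad_input")
  kw <- compare_groups(list(rnorm(10), rnorm(10) + 5, rnorm(10)),
                       test = "kruskal_wallis")
  expect_lt(kw$p_value, 0.01)
})

test_that("null Mann-Whitney p-values centre on 0.5", {
  set.seed(21)
  p <- replicate(200, {
    z <- rnorm(24)
    compare_groups(list(z[1:12], z[13:24]))$p_value
  })
  expect_gt(median(p), 0.35)
  expect_lt(median(p), 0.65)
})

test_that("midsection trends across planted classes are detected (n = 500)", {
  co <- generate_cohort(cohort_spec(n_patients = 500, seed = 17))
  pf <- aggregate_cohort(co$glomeruli)
  cls <- co$patients$true_class[match(pf$patient_id, co$patients$patient_id)]
  by_class <- function(col) split(pf[[col]][!is.na(pf[[col]])],
                                  cls[!is.na(pf[[col]])])
  expect_lt(compare_groups(by_class("ms_mesangial_area_fraction"),
                           "kruskal_wallis")$p_value, 0.01)
  expect_lt(compare_groups(by_class("ms_n_podocyte"),
                           "kruskal_wallis")$p_value, 0.01)
})
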