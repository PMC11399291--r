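# Pollution Index, rank classification, Pollution Load Index and
# clean-up-standard screening.

test_that("compute_pi is the concentration/background ratio and is scale invariant", {
  expect_equal(compute_pi(10, 5), 2)
  expect_equal(compute_pi(7.3, 7.3), 1)
  expect_equal(compute_pi(8.3 * 6, 6), 8.3)  # strongly enriched sample
  set.seed(11)
  conc <- runif(50, 0, 100); bg <- runif(50, 0.1, 10); k <- runif(50, 0.5, 20)
  expect_equal(compute_pi(k * conc, k * bg), compute_pi(conc, bg))
  expect_error(compute_pi(1, 0), "background")
  expect_error(compute_pi(-1, 2), ">= 0")
})

test_that("classify_pi ranks follow the printed left-closed intervals", {
  expect_equal(as.character(classify_pi(c(0, 0.5, 0.999))),
               rep("absent", 3))
  expect_equal(as.character(classify_pi(c(1, 1.999))), rep("low", 2))
  expect_equal(as.character(classify_pi(c(2, 2.999))), rep("moderate", 2))
  expect_equal(as.character(classify_pi(c(3, 4.999))), rep("strong", 2))
  expect_equal(as.character(classify_pi(c(5, 50, 1e6))),
               rep("very_strong", 3))
  expect_error(classify_pi(-0.1), ">= 0")
})

test_that("the five ranks tile [0, Inf) without overlap", {
  set.seed(7)
  pis <- c(runif(300, 0, 10), 0, 1, 2, 3, 5, 100)
  got <- as.character(classify_pi(pis))
  # independent scalar oracle
  oracle <- ifelse(pis < 1, "absent",
            ifelse(pis < 2, "low",
            ifelse(pis < 3, "moderate",
            ifelse(pis < 5, "strong", "very_strong"))))
  expect_equal(got, oracle)
  expect_false(anyNA(got))
})

test_that("compute_pli is the geometric mean with the hand-oracle value", {
  expect_equal(compute_pli(c(1, 1, 1, 1)), 1)
  expect_equal(compute_pli(c(2, 8, 1, 4)), 64^0.25, tolerance = 1e-12)
  expect_equal(compute_pli(3.7), 3.7)
  set.seed(21)
  p <- runif(6, 0.1, 9)
  expect_equal(compute_pli(p), compute_pli(sample(p)))
  expect_error(compute_pli(numeric(0)), "at least one")
  expect_warning(z <- compute_pli(c(2, 0, 4)), "zero")
  expect_equal(z, 0)
})

test_that("log(PLI) equals mean(log(PI)) and PLI is monotone and bounded", {
  set.seed(31)
  for (i in 1:20) {
    p <- runif(sample(2:8, 1), 0.01, 50)
    pli <- compute_pli(p)
    expect_equal(log(pli), mean(log(p)), tolerance = 1e-12)
    expect_gte(pli, min(p)); expect_lte(pli, max(p))
    j <- sample(length(p), 1)
    p2 <- p; p2[j] <- p2[j] * 1.5
    expect_gt(compute_pli(p2), pli)
  }
})

test_that("classify_pollution uses a strict threshold", {
  expect_false(classify_pollution(0.9))
  expect_false(classify_pollution(1.0))   # boundary: close to background
  expect_true(classify_pollution(1.0001))
  expect_true(classify_pollution(3.5))
  expect_equal(classify_pollution(c(1.4, 2), threshold = 1.5), c(FALSE, TRUE))
})

test_that("compute_indices assembles PI, ranks and PLI per sample", {
  s <- tiny_samples()
  idx <- compute_indices(s, tiny_background())
  expect_s3_class(idx, "pte_indices")
  expect_equal(idx$pi_As, s$As / 6)
  expect_equal(idx$pli[1],
               compute_pli(c(12 / 6, 0.7 / 0.35, 40 / 59.2, 50 / 69)))
  expect_equal(idx$polluted, idx$pli > 1)
  tidy <- tidy_indices(idx, s)
  expect_equal(nrow(tidy), 3 * 4)
  expect_equal(tidy$pi[tidy$sample_id == "a1" & tidy$element == "As"], 2)
})

test_that("a missing concentration drops the sample from PLI but keeps its PIs", {
  df <- tiny_samples_df()
  df$Pb[2] <- NA
  s <- read_samples(write_samples_csv(df))
  expect_warning(idx <- compute_indices(s, tiny_background()), "missing")
  expect_true(is.na(idx$pli[2]))
  expect_false(anyNA(idx$pi_As))
  expect_false(anyNA(idx$pli[c(1, 3)]))
})

test_that("element subset restricts the PLI and unknown elements need backgrounds", {
  s <- tiny_samples()
  idx <- compute_indices(s, tiny_background(), elements = c("As", "Cd"))
  expect_equal(idx$pli[1], compute_pli(c(2, 2)))
  expect_error(compute_indices(s, c(As = 6), elements = c("As", "Cd")),
               "background")
  # with no explicit subset the shared element set is used
  expect_equal(attr(compute_indices(s, c(As = 6)), "elements"), "As")
  # unknown elements flow through when a background is supplied
  df <- tiny_samples_df(); df$Hg <- c(0.1, 0.2, 0.3)
  s2 <- read_samples(write_samples_csv(df))
  idx2 <- compute_indices(s2, c(tiny_background(), Hg = 0.05))
  expect_true("pi_Hg" %in% names(idx2))
})

test_that("scs_exceedance counts strict exceedances per element and land use", {
  df <- data.frame(sample_id = sprintf("s%d", 1:4), site = "m",
                   x = 1:4, y = 1:4,
                   As = c(350, 20, 40, 10),     # 2 of 4 above 34
                   Cd = c(15, 15, 15, 15))      # all at the limit
  s <- read_samples(write_samples_csv(df))
  scs <- read_scs(system.file("extdata", "scs_default.csv",
                              package = "ptezone"))
  ex <- scs_exceedance(s, scs, elements = c("As", "Cd"))
  as_res <- ex[ex$element == "As" & ex$land_use == "residential", ]
  expect_equal(as_res$n_exceed, 2)
  expect_equal(as_res$pct, 50)
  expect_equal(as_res$frac, 0.5)
  expect_true(350 > as_res$limit)  # a 350 mg/kg sample exceeds
  cd_res <- ex[ex$element == "Cd" & ex$land_use == "residential", ]
  expect_equal(cd_res$n_exceed, 0)  # at the limit = compliant
  expect_error(scs_exceedance(s, scs, elements = "Hg"), "Hg")
})

test_that("summarize_site reports ranges, rank percentages and polluted fractions", {
  # one-sample site: min = median = max
  df1 <- tiny_samples_df()[1, ]
  s1 <- read_samples(write_samples_csv(df1))
  sm1 <- summarize_site(s1, compute_indices(s1, tiny_background()))
  e <- sm1$elements[sm1$elements$element == "As", ]
  expect_equal(e$conc_min, e$conc_median)
  expect_equal(e$conc_median, e$conc_max)

  # a 19-sample municipality: 16 polluted -> 84%, 18 very strong Cd -> 95%
  set.seed(5)
  n <- 19
  pli_target <- c(rep(2, 16), rep(0.5, 3))       # 16 of 19 polluted
  cd <- c(rep(5 * 0.35, 18), 0.2 * 0.35)         # 18 of 19 very strong
  df <- data.frame(sample_id = sprintf("b%02d", 1:n), site = "burit",
                   x = runif(n), y = runif(n),
                   As = 6 * pli_target, Cd = cd,
                   Pb = 59.2 * pli_target, Cr = 69 * pli_target)
  s <- read_samples(write_samples_csv(df))
  idx <- compute_indices(s, tiny_background())
  sm <- summarize_site(s, idx)
  expect_equal(round(sm$sites$pct_polluted), 84)
  rk <- sm$ranks[sm$ranks$element == "Cd" & sm$ranks$rank == "very_strong", ]
  expect_equal(round(rk$pct), 95)
  # even-n median uses the midpoint convention
  expect_equal(sm$elements$conc_median[sm$elements$element == "As"],
               median(df$As))
})
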