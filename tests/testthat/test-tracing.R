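# Condition-level labeling summaries and two-condition comparisons.

# build a minimal corrected-table stand-in for summary tests
fake_corrected <- function(values_by_group, metabolite = "lactate", j = 3) {
  rows <- lapply(names(values_by_group), function(g) {
    v <- values_by_group[[g]]
    tibble::tibble(sample = paste0(g, "_", seq_along(v)), group = g,
                   compartment = "media", metabolite = metabolite,
                   isotopologue = j, mid = v, pool = 1e6,
                   rel_abundance = v * 10, enrichment = v,
                   residual = 0, flagged = FALSE)
  })
  dplyr::bind_rows(rows)
}

test_that("labeling summaries report mean and SEM per group", {
  r0 <- summarize_labeling(fake_corrected(list(BSA = c(0.4, 0.4, 0.4))),
                           "lactate", 3)
  expect_equal(r0$mean, 0.4)
  expect_equal(r0$sem, 0)
  r <- summarize_labeling(
    fake_corrected(list(BSA = c(0.1, 0.2, 0.3), PA = c(0.4, 0.5, 0.6))),
    "lactate", 3)
  expect_equal(sort(r$mean), c(0.2, 0.5))
  expect_equal(r$sem, rep(sd(c(0.1, 0.2, 0.3)) / sqrt(3), 2))
  expect_equal(r$sem, rep(0.05774, 2), tolerance = 1e-4)
  # relative-abundance mode picks the normalized labeled abundance
  ra <- summarize_labeling(
    fake_corrected(list(BSA = c(0.1, 0.2, 0.3), PA = c(0.4, 0.5, 0.6))),
    "lactate", 3, mode = "relative_abundance")
  expect_equal(sort(ra$mean), c(2, 5))
  expect_error(summarize_labeling(fake_corrected(list(BSA = 0.1)),
                                  "citrate", 2), "citrate")
})

test_that("pooled t-test matches the closed-form oracle and handles degeneracy", {
  ident <- summarize_labeling(
    fake_corrected(list(A = c(1, 2, 3) / 10, B = c(1, 2, 3) / 10)), "lactate", 3)
  res <- compare_conditions(ident)
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
  r <- summarize_labeling(
    fake_corrected(list(A = c(.1, .2, .3), B = c(.4, .5, .6))), "lactate", 3)
  res <- compare_conditions(r)
  # closed form: sp = 0.1, se = 0.1*sqrt(2/3), t = -0.3/se, df = 4
  expect_equal(abs(res$t), 3.674, tolerance = 1e-3)
  expect_equal(res$df, 4)
  expect_equal(res$p, 2 * pt(-3 / sqrt(2 / 3), 4), tolerance = 1e-9)
  expect_equal(res$p, 0.0213, tolerance = 1e-3)
  # zero variance, unequal means: p underflows and is flagged
  dg <- compare_conditions(summarize_labeling(
    fake_corrected(list(A = c(.2, .2, .2), B = c(.4, .4, .4))), "lactate", 3))
  expect_equal(dg$p, 0)
  expect_true(dg$degenerate)
})

test_that("group swap flips the sign of t but not p", {
  r <- summarize_labeling(
    fake_corrected(list(A = c(.1, .25, .3), B = c(.42, .5, .61))), "lactate", 3)
  a <- compare_conditions(r)
  b <- compare_conditions(r[2:1, ])
  expect_equal(a$t, -b$t)
  expect_equal(a$p, b$p)
})

test_that("type-I error of the pooled t is nominal at n = 3", {
  set.seed(606)
  n_rep <- 4000
  a <- matrix(rnorm(3 * n_rep), ncol = 3)
  b <- matrix(rnorm(3 * n_rep), ncol = 3)
  p <- vapply(seq_len(n_rep), function(i)
    student_t_two_tailed(a[i, ], b[i, ])$p, numeric(1))
  expect_gte(mean(p < 0.05), 0.04)
  expect_lte(mean(p < 0.05), 0.06)
})

test_that("sample-wide area scaling cancels in MIDs, scales abundances", {
  fx <- bundled_fixture("glucose_6h", seed = 33)
  cs1 <- correct_samples(fx$areas, fx$design)
  areas2 <- fx$areas
  chan_cols <- setdiff(names(areas2), "sample")
  areas2[1, chan_cols] <- areas2[1, chan_cols] * 7
  cs2 <- correct_samples(areas2, fx$design)
  s1 <- cs1[cs1$sample == areas2$sample[1], ]
  s2 <- cs2[cs2$sample == areas2$sample[1], ]
  expect_equal(s2$mid, s1$mid, tolerance = 1e-9)
  expect_equal(s2$rel_abundance, 7 * s1$rel_abundance, tolerance = 1e-9)
  rest1 <- cs1[cs1$sample != areas2$sample[1], ]
  rest2 <- cs2[cs2$sample != areas2$sample[1], ]
  expect_equal(rest2$mid, rest1$mid, tolerance = 1e-12)
})

test_that("media-transfer join keeps shared keys and recovers uptake slope", {
  donor <- dplyr::bind_rows(
    summarize_labeling(fake_corrected(list(BSA = c(.3, .3), PA = c(.4, .4))),
                       "lactate", 3),
    summarize_labeling(fake_corrected(list(BSA = c(.1, .1), PA = c(.2, .2)),
                                      metabolite = "succinate", j = 2),
                       "succinate", 2))
  recipient <- summarize_labeling(
    fake_corrected(list(BSA = c(.31, .29), PA = c(.41, .39))), "lactate", 3)
  recipient_extra <- dplyr::bind_rows(
    recipient,
    summarize_labeling(fake_corrected(list(BSA = c(.1, .1), PA = c(.1, .1)),
                                      metabolite = "citrate", j = 2),
                       "citrate", 2))
  expect_message(tab <- media_transfer_table(donor, recipient_extra),
                 "recipient-only")
  expect_equal(sort(unique(tab$metabolite)), "lactate")
  expect_equal(nrow(tab), 2)  # one row per group
  expect_error(media_transfer_table(donor[donor$metabolite == "succinate", ],
                                    recipient), "no shared")

  # fixture: recipient cells carry 30% of the donor-media labeled pool
  fx <- bundled_fixture("glucose_6h", seed = 77)
  cs <- correct_samples(fx$areas, fx$design)
  keys <- expand.grid(metabolite = c("lactate", "itaconate", "succinate"),
                      stringsAsFactors = FALSE)
  keys$j <- c(3, 1, 2)
  readouts <- function(comp) dplyr::bind_rows(lapply(seq_len(nrow(keys)),
    function(i) summarize_labeling(cs, keys$metabolite[i], keys$j[i],
                                   mode = "relative_abundance",
                                   compartment = comp)))
  tab <- media_transfer_table(readouts("media"), readouts("recipient-cell"))
  slope <- sum(tab$donor_mean * tab$recipient_mean) / sum(tab$donor_mean^2)
  expect_equal(slope, 0.3, tolerance = 0.1)
})
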