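# a dset whose within/between groups have configurable mean shift
shifted_dset <- function(seed, delta, n = 400) {
  withr::with_seed(seed, {
    sa <- sample(which(the_pairs$type == "SA"), n / 2, replace = TRUE)
    dn <- sample(which(the_pairs$type == "DN"), n / 2, replace = TRUE)
    idx <- c(sa, dn)
    d <- 1.4 + rnorm(n, sd = 0.1) + c(rep(0, n / 2), rep(delta, n / 2))
    fake_dset(
      i = the_pairs$i[idx], j = the_pairs$j[idx],
      delay = rep(1:20, length.out = n), d = d
    )
  })
}

test_that("community sensitivity recovers a known group difference exactly", {
  d <- shifted_dset(1, delta = 0.2)
  res <- community_sensitivity(d, the_pairs)
  within <- d$d_corr[1:200]
  between <- d$d_corr[201:400]
  expect_equal(res$d_w, mean(within))
  expect_equal(res$d_b, mean(between))
  expect_equal(res$delta_bw, mean(between) - mean(within)) # exact identity
  oracle <- stats::t.test(between, within, var.equal = TRUE)
  expect_equal(res$t_bw, unname(oracle$statistic))
  expect_equal(res$p, oracle$p.value)
  # group sizes + means reconstruct the grand mean
  expect_equal(
    (res$n_w * res$d_w + res$n_b * res$d_b) / (res$n_w + res$n_b),
    mean(d$d_corr)
  )
})

test_that("swapping group labels flips the sign of the statistic", {
  d <- shifted_dset(2, delta = 0.15)
  res <- community_sensitivity(d, the_pairs)
  # relabel: make SA/SN pairs between and DA/DN within by inverting communities
  swapped <- the_pairs
  swapped$type <- factor(
    c(SA = "DN", DA = "SN", SN = "DA", DN = "SA")[as.character(the_pairs$type)],
    levels = levels(the_pairs$type)
  )
  res2 <- community_sensitivity(d, swapped)
  expect_equal(res2$delta_bw, -res$delta_bw)
  expect_equal(res2$t_bw, -res$t_bw, tolerance = 1e-8)
})

test_that("latency bounds and same-object pairs are respected", {
  d <- shifted_dset(3, delta = 0.3)
  same <- fake_dset(i = rep(4L, 50), j = rep(4L, 50), delay = rep(2L, 50), d = 0.1)
  both <- rbind(d, same)
  # same-object pairs never enter community statistics
  expect_equal(
    community_sensitivity(both, the_pairs)$delta_bw,
    community_sensitivity(d, the_pairs)$delta_bw
  )
  # latency bound subsets pairs
  res10 <- community_sensitivity(d, the_pairs, tau_lb = 10)
  keep <- d$delay >= 10
  expect_identical(res10$n_w + res10$n_b, sum(keep))
  expect_error(
    community_sensitivity(d[d$delay <= 2, ], the_pairs, tau_lb = 5),
    "insufficient"
  )
})

test_that("tau_sig is the largest bound with uninterrupted significance", {
  # strong persistent effect: significant at every bound
  d <- shifted_dset(4, delta = 0.3, n = 2000)
  rep1 <- latency_sweep(list(p1 = d), the_pairs, tau_max = 10)
  expect_identical(rep1$tau_sig, 10L)
  expect_true(rep1$sensitive)
  expect_identical(rep1$sign, 1)
  # no effect: tau_sig 0 almost surely
  d0 <- shifted_dset(5, delta = 0, n = 2000)
  rep0 <- latency_sweep(list(p1 = d0), the_pairs, tau_max = 10)
  expect_false(rep0$sensitive)
  # effect confined to short latencies: the run of significance breaks
  dd <- shifted_dset(6, delta = 0, n = 4000)
  short <- dd$delay <= 3
  within_short <- short & dd$i <= 5 & dd$j <= 5
  dd$d_corr[within_short] <- dd$d_corr[within_short] - 0.5
  repS <- latency_sweep(list(p1 = dd), the_pairs, tau_max = 10)
  expect_lt(repS$tau_sig, 10L)
  # decreasing q can only shorten the significant run
  repq <- latency_sweep(list(p1 = d), the_pairs, tau_max = 10, q = 1e-12)
  expect_lte(repq$tau_sig, rep1$tau_sig)
})

test_that("FDR is applied across parcels within each bound", {
  strong <- shifted_dset(7, delta = 0.3, n = 1000)
  nulls <- lapply(8:13, shifted_dset, delta = 0, n = 1000)
  dsets <- c(list(strong = strong), stats::setNames(nulls, paste0("null", 1:6)))
  report <- latency_sweep(dsets, the_pairs, tau_max = 5)
  expect_identical(report$parcel_id[1], "strong")
  p_raw <- attr(report, "sweep_p")
  p_adj <- attr(report, "sweep_p_adj")
  for (b in 1:5) {
    expect_equal(p_adj[, b], fdr_adjust(p_raw[, b]), ignore_attr = TRUE)
  }
  expect_true(all(p_adj >= p_raw - 1e-15))
})

test_that("pair-type statistics compare each type against the pooled reference", {
  withr::with_seed(11, {
    idx <- rep(seq_len(nrow(the_pairs)), 30)
    d <- 1.4 + rnorm(length(idx), sd = 0.1)
  })
  # make SA pairs closer by 0.1
  sa <- the_pairs$type[idx] == "SA"
  d[sa] <- d[sa] - 0.1
  dset <- fake_dset(
    i = the_pairs$i[idx], j = the_pairs$j[idx],
    delay = rep(1:30, length.out = length(idx)), d = d
  )
  st <- pair_type_stats(dset, the_pairs)
  expect_identical(st$type, c("SA", "DA", "SN", "DN"))
  expect_identical(st$n, as.integer(30 * c(27, 3, 3, 72)))
  expect_lt(st$t[st$type == "SA"], -5)
  # definitional check: the pool contains the tested type's own members
  oracle <- stats::t.test(d[sa], d, var.equal = TRUE)
  expect_equal(st$t[st$type == "SA"], unname(oracle$statistic))
  # absent type flagged
  sub <- dset[the_pairs$type[idx] != "DA", ]
  expect_warning(st2 <- pair_type_stats(sub, the_pairs), "DA")
  expect_true(is.na(st2$t[st2$type == "DA"]))
})

test_that("BH adjustment matches the hand-computed step-up oracle", {
  expect_equal(fdr_adjust(rep(0.01, 10)), rep(0.01, 10))
  expect_equal(
    fdr_adjust(c(0.01, 0.04, 0.03, 0.005)),
    c(0.02, 0.04, 0.04, 0.02)
  )
  expect_identical(fdr_adjust(0.37), 0.37)
  expect_true(all(diff(sort(fdr_adjust(runif(50)))) >= 0))
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(fdr_adjust(c(0.5, NA)), "\\[0, 1\\]")
})

test_that("null replicates reject near the nominal rate and power grows with beta", {
  # trial-level null: independent distances, single parcel, no FDR
  rejections <- vapply(1:200, function(s) {
    d <- shifted_dset(1000 + s, delta = 0, n = 300)
    community_sensitivity(d, the_pairs)$p < 0.05
  }, logical(1))
  expect_gt(mean(rejections), 0.02)
  expect_lt(mean(rejections), 0.09)
  # monotone power in the shift magnitude
  power_at <- function(delta) {
    mean(vapply(1:40, function(s) {
      community_sensitivity(shifted_dset(2000 + s, delta, n = 300), the_pairs)$p < 0.05
    }, logical(1)))
  }
  p0 <- power_at(0.01)
  p1 <- power_at(0.05)
  p2 <- power_at(0.15)
  expect_lte(p0, p1 + 0.1)
  expect_lte(p1, p2)
  expect_gt(p2, 0.9)
})
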