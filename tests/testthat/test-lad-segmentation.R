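# deterministic synthetic track with planted state blocks and Student-t noise
make_t_track <- function(n = 300, mu = c(-1, 1), sigma = 0.5, nu = 5,
                         block = 25, chrom = "chrA", seed = 1) {
  set.seed(seed)
  states <- rep(rep(1:2, length.out = ceiling(n / block)), each = block)[1:n]
  x <- mu[states] + sigma * rt(n, df = nu)
  list(track = structure(
    data.frame(chrom = chrom, start = (seq_len(n) - 1L) * 1e5,
               end = seq_len(n) * 1e5, score = x),
    class = c("score_track", "data.frame")),
    states = states)
}

test_that("HMM recovers planted blocks with high state accuracy", {
  sim <- make_t_track(n = 1000, mu = c(-1.5, 1.5), sigma = 1, seed = 42)
  fit <- fit_segment_hmm(sim$track)
  acc <- mean(fit$path$state == sim$states)
  expect_gte(acc, 0.95)
  expect_true(fit$model$converged)
  # transition rows sum to 1, scales positive, LAD state has larger mu
  expect_equal(rowSums(fit$model$transition), c(1, 1), tolerance = 1e-9)
  expect_true(all(fit$model$sigma > 0))
  expect_gt(fit$model$mu[2], fit$model$mu[1])
})

test_that("EM log-likelihood is non-decreasing and initialization order does not matter", {
  sim <- make_t_track(n = 250, seed = 7)
  fit <- fit_segment_hmm(sim$track)
  expect_true(all(diff(fit$model$loglik_trace) >=
                    -1e-8 * pmax(1, abs(utils::head(fit$model$loglik_trace,
                                                    -1)))))
  f1 <- fit_segment_hmm(sim$track, init = list(mu = c(-1, 1)))
  f2 <- fit_segment_hmm(sim$track, init = list(mu = c(1, -1)))
  expect_equal(f1$path$state, f2$path$state)
  expect_equal(f1$model$mu, f2$model$mu, tolerance = 1e-4)
})

test_that("degenerate and missing-chromosome inputs are handled", {
  const <- structure(data.frame(chrom = "c", start = 0:19 * 1e5,
                                end = 1:20 * 1e5, score = 1.7),
                     class = c("score_track", "data.frame"))
  expect_error(fit_segment_hmm(const), "degenerate|constant")

  sim <- make_t_track(n = 60, seed = 3)
  tr <- sim$track
  extra <- tr[1:5, ]
  extra$chrom <- "empty"
  extra$score <- NA_real_
  tr2 <- rbind(tr, extra)
  expect_warning(fit <- fit_segment_hmm(tr2), "all-missing")
  expect_equal(nrow(fit$path), 60L)
})

test_that("missing observations are marginalized and can be bridged in calls", {
  sim <- make_t_track(n = 200, mu = c(-2, 2), sigma = 0.5, seed = 9)
  tr <- sim$track
  # blank a couple of interior bins inside state-2 blocks
  inside2 <- which(sim$states == 2)
  holes <- inside2[c(10, 11, 40)]
  tr$score[holes] <- NA
  fit <- fit_segment_hmm(tr)
  lads_b <- call_lads(fit, bridge_missing = TRUE)
  lads_s <- call_lads(fit, bridge_missing = FALSE)
  cover <- function(l) sum(l$end - l$start)
  expect_gte(cover(lads_b), cover(lads_s))
  expect_gte(nrow(lads_s), nrow(lads_b))
})

test_that("Viterbi equals brute-force enumeration for short sequences", {
  set.seed(13)
  for (rep in 1:25) {
    Tn <- sample(2:12, 1)
    x <- rnorm(Tn)
    mu <- sort(rnorm(2, sd = 1.5)); sigma <- runif(2, 0.3, 1.2)
    em <- laminatools:::emission_matrix(x, mu, sigma, 5)
    a <- runif(2, 0.6, 0.95)
    A <- rbind(c(a[1], 1 - a[1]), c(1 - a[2], a[2]))
    lpi <- log(c(0.5, 0.5))
    expect_equal(laminatools:::viterbi_path(em, log(A), lpi),
                 oracle_best_path(em, log(A), lpi))
  }
})

test_that("call_lads merges runs, never crosses chromosomes, and handles empty paths", {
  path <- data.frame(chrom = "c1", start = 0:5 * 1e5, end = 1:6 * 1e5,
                     state = c(2, 2, 2, 1, 1, 2), missing = FALSE)
  lads <- call_lads(path)
  expect_equal(lads$start, c(0, 5e5))
  expect_equal(lads$end, c(3e5, 6e5))

  empty <- call_lads(path[0, ])
  expect_equal(nrow(empty), 0L)

  # run continuing across a chromosome boundary splits into two LADs
  path2 <- data.frame(chrom = rep(c("chr2L", "chr2R"), each = 3),
                      start = rep(0:2 * 1e5, 2), end = rep(1:3 * 1e5, 2),
                      state = 2, missing = FALSE)
  lads2 <- call_lads(path2)
  expect_equal(nrow(lads2), 2L)
  expect_setequal(lads2$chrom, c("chr2L", "chr2R"))

  # output intervals are disjoint and cover exactly the LAD-state intervals
  sim <- make_t_track(n = 120, seed = 17)
  fit <- fit_segment_hmm(sim$track)
  l <- call_lads(fit)
  if (nrow(l) > 1) {
    expect_true(all(l$start[-1] >= l$end[-nrow(l)]))
  }
  in_lad <- rep(FALSE, 120)
  for (i in seq_len(nrow(l)))
    in_lad <- in_lad | (sim$track$start >= l$start[i] &
                          sim$track$end <= l$end[i])
  expect_equal(in_lad, fit$path$state == 2L)
})

test_that("lad_stats returns count and mean length with an explicit empty sentinel", {
  l <- lad_set(data.frame(chrom = "c", start = c(0L, 500000L),
                          end = c(300000L, 600000L)))
  s <- lad_stats(l)
  expect_equal(s$count, 2L)
  expect_equal(s$mean_length_kb, 200)

  e <- lad_stats(lad_set(NULL))
  expect_equal(e$count, 0L)
  expect_true(is.na(e$mean_length_kb))
})

test_that("region comparison matches exact rank-sum enumeration", {
  cyto <- data.frame(chrom = "chrA",
                     start = c(0, 2e6, 4e6), end = c(2e6, 4e6, 6e6),
                     name = c("21A", "cen1", "22B"),
                     gieStain = c("n/a", "acen", "n/a"))
  part <- region_partition(cyto, telomere_span = 3e5)
  # three arm bins scoring {1,2,3}, three centromere bins scoring {4,5,6}
  tr <- structure(data.frame(
    chrom = "chrA",
    start = c(5e5, 8e5, 11e5, 25e5, 28e5, 31e5),
    end = c(6e5, 9e5, 12e5, 26e5, 29e5, 32e5),
    score = c(1, 2, 3, 4, 5, 6)),
    class = c("score_track", "data.frame"))
  rc <- region_comparison(tr, part, regions = c("arm", "centromere"))
  expect_equal(sort(rc$scores$arm), c(1, 2, 3))
  expect_equal(sort(rc$scores$centromere), c(4, 5, 6))
  row <- rc$pairwise[rc$pairwise$region_a == "arm", ]
  expect_equal(row$U, 0)
  expect_equal(row$p_value, 0.1)       # 2 * 1/20 over C(6,3) labelings
  expect_equal(row$p_value, oracle_mw_exact_p(c(1, 2, 3), c(4, 5, 6)))
  expect_true(row$exact)

  # identical samples give exact p = 1
  tr2 <- tr
  tr2$score <- c(1, 2, 3, 1, 2, 3)
  rc2 <- region_comparison(tr2, part, regions = c("arm", "centromere"))
  expect_equal(rc2$pairwise$p_value, 1)

  # empty region errors by name
  expect_error(region_comparison(tr, part), "telomere")
})
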