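## Two-state hidden Markov model with Student-t emissions, for segmenting
## DamID score tracks into lamina-associated (high-score) and detached
## (low-score) states. Baum-Welch EM in log space; missing observations are
## marginalized (emission likelihood 1); the heavy-tailed t emission makes
## the segmentation robust to score outliers.

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log density of scaled/shifted Student-t
ldt <- function(x, mu, sigma, nu)
  stats::dt((x - mu) / sigma, df = nu, log = TRUE) - log(sigma)

# forward-backward for one sequence; em = T x 2 log emission matrix
# returns log-likelihood, gamma (T x 2), and xi_sum (2 x 2)
forward_backward <- function(em, lA, lpi) {
  Tn <- nrow(em)
  la <- matrix(-Inf, Tn, 2)
  lb <- matrix(0, Tn, 2)
  la[1, ] <- lpi + em[1, ]
  for (t in seq_len(Tn)[-1]) {
    for (j in 1:2)
      la[t, j] <- logsumexp(la[t - 1, ] + lA[, j]) + em[t, j]
  }
  ll <- logsumexp(la[Tn, ])
  for (t in rev(seq_len(Tn - 1))) {
    for (i in 1:2)
      lb[t, i] <- logsumexp(lA[i, ] + em[t + 1, ] + lb[t + 1, ])
  }
  lg <- la + lb - ll
  gamma <- exp(lg)
  xi <- matrix(0, 2, 2)
  if (Tn > 1) {
    for (i in 1:2) for (j in 1:2) {
      lx <- la[seq_len(Tn - 1), i] + lA[i, j] +
        em[seq_len(Tn)[-1], j] + lb[seq_len(Tn)[-1], j] - ll
      xi[i, j] <- sum(exp(lx))
    }
  }
  list(ll = ll, gamma = gamma, xi = xi)
}

viterbi_path <- function(em, lA, lpi) {
  Tn <- nrow(em)
  delta <- matrix(-Inf, Tn, 2)
  psi <- matrix(0L, Tn, 2)
  delta[1, ] <- lpi + em[1, ]
  for (t in seq_len(Tn)[-1]) {
    for (j in 1:2) {
      v <- delta[t - 1, ] + lA[, j]
      psi[t, j] <- which.max(v)
      delta[t, j] <- v[psi[t, j]] + em[t, j]
    }
  }
  path <- integer(Tn)
  path[Tn] <- which.max(delta[Tn, ])
  for (t in rev(seq_len(Tn - 1)))
    path[t] <- psi[t + 1, path[t + 1]]
  path
}

#' Fit a two-state Student-t HMM to a score track and segment it
#'
#' Each chromosome is treated as an independent observation sequence of one
#' shared model. Emissions are Student-t with per-state location `mu` and
#' scale `sigma` and a shared degrees-of-freedom `nu` (default 5, optionally
#' estimated). Parameters are fitted by Baum-Welch EM in log space; the
#' Student-t M-step uses the standard auxiliary-scale weighting, so the
#' observed-data log-likelihood is non-decreasing (checked at every
#' iteration). Missing scores contribute emission likelihood 1, i.e. they
#' are marginalized while the transition chain runs through them. After
#' convergence states are relabeled so that state 2 is the high-score (LAD)
#' state, and the final state path is computed by Viterbi decoding.
#'
#' @param track A [score_track()] result (or any `data.frame` with `chrom`,
#'   `start`, `end`, `score`, `NA` = missing).
#' @param init Optional list overriding initialization: elements `mu`
#'   (length 2), `sigma` (length 2), `self_transition` (scalar in (0,1)).
#'   By default `mu` is the 25th/75th percentile of the observed scores,
#'   `sigma` half the interquartile range, and self-transitions 0.9.
#' @param tolerance Absolute log-likelihood change at which EM stops.
#' @param max_iter Maximum EM iterations.
#' @param nu Degrees of freedom (positive scalar), or `"estimate"` to
#'   maximize it numerically each iteration.
#' @return A list of class `segment_fit` with
#'   \describe{
#'     \item{model}{`mu`, `sigma`, `nu`, `transition` (2x2, rows sum to 1),
#'       `init_prob`, `loglik_trace`, `converged`, `lad_state` (always 2
#'       after relabeling)}
#'     \item{path}{`data.frame` `chrom`, `start`, `end`, `state` (1/2),
#'       `missing`}
#'   }
#' @export
fit_segment_hmm <- function(track, init = NULL, tolerance = 1e-6,
                            max_iter = 200L, nu = 5) {
  x_all <- track$score
  chroms <- unique(track$chrom)
  use <- vapply(chroms, function(ch)
    sum(!is.na(x_all[track$chrom == ch])) > 0L, logical(1))
  if (any(!use))
    warning("skipping all-missing chromosome(s): ",
            paste(chroms[!use], collapse = ", "))
  chroms <- chroms[use]
  if (!length(chroms)) stop("no chromosome with observations")
  obs <- x_all[track$chrom %in% chroms & !is.na(x_all)]
  if (stats::sd(obs) == 0)
    stop("degenerate fit: observations are constant (zero variance)")

  estimate_nu <- identical(nu, "estimate")
  nu_val <- if (estimate_nu) 5 else as.numeric(nu)
  stopifnot(nu_val > 0)

  q <- stats::quantile(obs, c(0.25, 0.75), names = FALSE)
  mu <- if (!is.null(init$mu)) init$mu else q
  iqr2 <- max((q[2] - q[1]) / 2, 1e-3)
  sigma <- if (!is.null(init$sigma)) init$sigma else rep(iqr2, 2)
  p_self <- if (!is.null(init$self_transition)) init$self_transition else 0.9
  A <- matrix(c(p_self, 1 - p_self, 1 - p_self, p_self), 2, 2, byrow = TRUE)
  pi0 <- c(0.5, 0.5)

  seqs <- lapply(chroms, function(ch) x_all[track$chrom == ch])

  total_ll <- function(mu, sigma, nu_val, A, pi0) {
    lA <- log(A); lpi <- log(pi0)
    sum(vapply(seqs, function(x) {
      em <- emission_matrix(x, mu, sigma, nu_val)
      forward_backward(em, lA, lpi)$ll
    }, numeric(1)))
  }

  ll_trace <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    lA <- log(A); lpi <- log(pi0)
    ll <- 0
    g_list <- vector("list", length(seqs))
    xi_sum <- matrix(0, 2, 2)
    pi_acc <- c(0, 0)
    for (k in seq_along(seqs)) {
      em <- emission_matrix(seqs[[k]], mu, sigma, nu_val)
      fb <- forward_backward(em, lA, lpi)
      ll <- ll + fb$ll
      g_list[[k]] <- fb$gamma
      xi_sum <- xi_sum + fb$xi
      pi_acc <- pi_acc + fb$gamma[1, ]
    }
    if (ll < ll_prev - 1e-8 * max(1, abs(ll_prev)))
      stop("internal error: EM log-likelihood decreased (",
           ll_prev, " -> ", ll, ")")
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_prev) && abs(ll - ll_prev) < tolerance) {
      converged <- TRUE
      break
    }
    ll_prev <- ll

    # M-step
    A <- xi_sum / pmax(rowSums(xi_sum), .Machine$double.eps)
    A <- pmax(A, 1e-12); A <- A / rowSums(A)
    pi0 <- pi_acc / sum(pi_acc)
    x <- unlist(seqs)
    g <- do.call(rbind, g_list)
    ok <- !is.na(x)
    xo <- x[ok]; go <- g[ok, , drop = FALSE]
    for (s in 1:2) {
      z2 <- ((xo - mu[s]) / sigma[s])^2
      u <- (nu_val + 1) / (nu_val + z2)
      w <- go[, s]
      mu_new <- sum(w * u * xo) / sum(w * u)
      sigma2 <- sum(w * u * (xo - mu_new)^2) / sum(w)
      mu[s] <- mu_new
      sigma[s] <- sqrt(max(sigma2, 1e-12))
    }
    if (estimate_nu) {
      opt <- stats::optimize(function(v) total_ll(mu, sigma, v, A, pi0),
                             interval = c(0.5, 100), maximum = TRUE,
                             tol = 1e-2)
      if (opt$objective >= total_ll(mu, sigma, nu_val, A, pi0))
        nu_val <- opt$maximum
    }
  }

  # relabel: state 2 = larger mu (LAD)
  if (mu[1] > mu[2]) {
    perm <- c(2L, 1L)
    mu <- mu[perm]; sigma <- sigma[perm]
    A <- A[perm, perm]; pi0 <- pi0[perm]
  }

  lA <- log(A); lpi <- log(pi0)
  states <- integer(0)
  for (k in seq_along(seqs)) {
    em <- emission_matrix(seqs[[k]], mu, sigma, nu_val)
    states <- c(states, viterbi_path(em, lA, lpi))
  }
  keep <- track$chrom %in% chroms
  path <- data.frame(chrom = track$chrom[keep], start = track$start[keep],
                     end = track$end[keep], state = states,
                     missing = is.na(x_all[keep]),
                     stringsAsFactors = FALSE)

  structure(list(
    model = list(mu = mu, sigma = sigma, nu = nu_val, transition = A,
                 init_prob = pi0, loglik_trace = ll_trace,
                 converged = converged, lad_state = 2L),
    path = path), class = "segment_fit")
}

emission_matrix <- function(x, mu, sigma, nu) {
  em <- matrix(0, length(x), 2)
  ok <- !is.na(x)
  for (s in 1:2) em[ok, s] <- ldt(x[ok], mu[s], sigma[s], nu)
  em  # missing rows stay 0 = log(1)
}

#' @export
print.segment_fit <- function(x, ...) {
  m <- x$model
  cat("Two-state Student-t HMM fit\n",
      sprintf("  mu    = %.4f / %.4f\n", m$mu[1], m$mu[2]),
      sprintf("  sigma = %.4f / %.4f\n", m$sigma[1], m$sigma[2]),
      sprintf("  nu    = %.3f\n", m$nu),
      sprintf("  iterations = %d (converged: %s)\n",
              length(m$loglik_trace), m$converged), sep = "")
  invisible(x)
}
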