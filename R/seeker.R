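#' Classify sites of a test haplotype into the four observation states
#'
#' Each site of a polarized panel is assigned one of four marker states for
#' a given test haplotype, driven by derived-allele sharing with the
#' reference panels:
#' \describe{
#'   \item{1, test-population-specific}{test carries the derived allele;
#'     no archaic and no African reference carries it.}
#'   \item{2, archaic marker}{test carries the derived allele; it is found
#'     in at least one archaic reference but in no African reference.}
#'   \item{3, modern-human (AMH) marker}{test carries the derived allele;
#'     it is found in Africans but in no archaic reference.}
#'   \item{4, common}{everything else, including every site where the test
#'     haplotype carries the ancestral allele.}
#' }
#' Missing reference genotypes are uninformative: a missing call never
#' counts as carrying the derived allele.
#'
#' @param panel a polarized [site_panel()].
#' @param haplotype haplotype id or column index; must have role `test`.
#' @return integer vector of states in 1..4, aligned to the panel sites.
#' @export
classify_observations <- function(panel, haplotype) {
  if (!panel$polarized) stop("panel must be polarized first")
  h <- if (is.character(haplotype)) match(haplotype, panel$hap)
       else as.integer(haplotype)
  if (is.na(h) || h < 1L || h > ncol(panel$geno))
    stop("unknown haplotype: ", haplotype)
  if (panel$roles[h] != "test")
    stop("haplotype ", panel$hap[h], " does not have role 'test'")
  sh <- .sharing_flags(panel)
  .classify_one(panel$geno[, h], sh$arch, sh$afr)
}

.sharing_flags <- function(panel) {
  arch_i <- role_index(panel, "archaic_ref")
  afr_i <- role_index(panel, "african_ref")
  if (!length(arch_i)) stop("panel has no archaic reference haplotypes")
  if (!length(afr_i)) stop("panel has no African reference haplotypes")
  list(arch = rowSums(panel$geno[, arch_i, drop = FALSE] == 1L,
                      na.rm = TRUE) > 0L,
       afr = rowSums(panel$geno[, afr_i, drop = FALSE] == 1L,
                     na.rm = TRUE) > 0L)
}

.classify_one <- function(g, arch, afr) {
  st <- rep(4L, length(g))
  der <- !is.na(g) & g == 1L
  st[der & !arch & !afr] <- 1L
  st[der & arch & !afr] <- 2L
  st[der & !arch & afr] <- 3L
  st
}

#' Observation matrix for all test haplotypes
#' @param panel a polarized [site_panel()].
#' @return integer matrix, sites x test haplotypes, values in 1..4.
#' @export
observation_matrix <- function(panel) {
  sh <- .sharing_flags(panel)
  test_i <- role_index(panel, "test")
  if (!length(test_i)) stop("panel has no test haplotypes")
  obs <- vapply(test_i, function(h)
    .classify_one(panel$geno[, h], sh$arch, sh$afr),
    integer(length(panel$pos)))
  obs <- matrix(obs, nrow = length(panel$pos))
  colnames(obs) <- panel$hap[test_i]
  obs
}

#' Transition matrix of the introgression HMM
#'
#' Pulse-admixture two-state Markov transition over a genetic distance `d`
#' (Morgans): with introgression proportion `alpha` and time `T`
#' (generations),
#' `P(AMH -> archaic) = alpha (1 - exp(-T d))` and
#' `P(archaic -> AMH) = (1 - alpha)(1 - exp(-T d))`; the diagonal entries
#' are the complements.  At `d = 0` this is the identity; as `d` grows both
#' rows tend to the stationary distribution `(1 - alpha, alpha)`.
#'
#' @param d genetic distance in Morgans (non-negative scalar).
#' @param params a list with elements `alpha` and `T` (see [em_fit()]).
#' @return a 2x2 row-stochastic matrix, rows/cols `c("AMH", "archaic")`.
#' @export
transition_matrix <- function(d, params) {
  stopifnot(d >= 0)
  q <- 1 - exp(-params$T * d)
  a01 <- params$alpha * q
  a10 <- (1 - params$alpha) * q
  matrix(c(1 - a01, a10, a01, 1 - a10), 2, 2,
         dimnames = list(c("AMH", "archaic"), c("AMH", "archaic")))
}

#' Initial emission matrix from genome-wide state frequencies
#'
#' The initialization is governed by a single parameter `epsilon` (default
#' 0.99).  Row AMH concentrates mass `epsilon` on the states expected on a
#' modern-human background (AMH markers and common markers, split in
#' proportion to their genome-wide frequencies) and `1 - epsilon` on states
#' 1 and 2.  Row archaic concentrates `epsilon` on states 1, 2 and 4
#' (frequency-proportional) and leaves `1 - epsilon` on the AMH-marker
#' state, which an archaic haplotype should essentially never emit.
#'
#' @param freq numeric length-4 vector of genome-wide observation-state
#'   frequencies.
#' @param epsilon emission-initialization parameter in (0, 1).
#' @return 2x4 row-stochastic matrix (rows: AMH, archaic).
#' @export
emission_init <- function(freq, epsilon = 0.99) {
  f <- pmax(freq / sum(freq), 1e-8)
  e0 <- c((1 - epsilon) * f[1:2] / sum(f[1:2]),
          epsilon * f[3:4] / sum(f[3:4]))
  e1 <- c(epsilon * f[1] / sum(f[c(1, 2, 4)]),
          epsilon * f[2] / sum(f[c(1, 2, 4)]),
          1 - epsilon,
          epsilon * f[4] / sum(f[c(1, 2, 4)]))
  e <- rbind(AMH = e0, archaic = e1)
  colnames(e) <- paste0("state", 1:4)
  e / rowSums(e)
}

#' Fit the introgression HMM by constrained EM
#'
#' Pools all test haplotypes of the panel through scaled forward-backward
#' passes and iterates: the introgression proportion `alpha` is updated
#' from the marginal archaic posterior, the introgression time `T` by
#' maximizing the expected transition log-likelihood (one-dimensional
#' search on log `T`), and six of the eight emission entries from expected
#' emission counts.  Two entries stay frozen at their `epsilon`-derived
#' initial values: `P(archaic marker | AMH)`, so that genuine archaic
#' markers are never absorbed into the modern-human state, and
#' `P(test-specific marker | archaic)`, so that bursts of
#' population-private variation are not mistaken for archaic sequence --
#' the false-detection guard.  Iteration
#' stops when the relative change of the pooled log-likelihood drops below
#' `tol` or after `max_iter` iterations; the log-likelihood trace is
#' non-decreasing up to numerical noise.
#'
#' @param obs observation matrix from [observation_matrix()] (sites x test
#'   haplotypes), or `NULL` to build it from `panel`.
#' @param panel a polarized [site_panel()] with genetic positions attached
#'   (the 1 cM/Mb fallback is applied when absent).
#' @param alpha0,t0 initial introgression proportion and time
#'   (generations); defaults 0.02 and 2000.
#' @param epsilon emission-initialization parameter, default 0.99.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter maximum EM iterations.
#' @return a list of class `"hmm_params"`: `alpha`, `T`, `emission`,
#'   `epsilon`, `loglik` (trace), `converged`, `freq` (state frequencies),
#'   `frozen` (the two frozen entries).
#' @export
em_fit <- function(obs = NULL, panel, alpha0 = 0.02, t0 = 2000,
                   epsilon = 0.99, tol = 1e-5, max_iter = 200L) {
  if (is.null(panel$gpos)) panel <- attach_genetic_map(panel, NULL)
  if (is.null(obs)) obs <- observation_matrix(panel)
  if (nrow(obs) != length(panel$pos)) stop("obs/panel site mismatch")
  if (all(obs == 4L)) stop("no markers: every site is in the common state")
  d <- pmax(diff(panel$gpos), 1e-9)
  freq <- tabulate(obs, 4L) / length(obs)
  e <- emission_init(freq, epsilon)
  frozen <- c(e[1, 2], e[2, 1])
  alpha <- alpha0; Tg <- t0
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    es <- .hmm_estep(obs, d, e, alpha, Tg)
    trace <- c(trace, es$loglik)
    if (it > 1L) {
      rel <- abs(trace[it] - trace[it - 1L]) /
        max(1, abs(trace[it - 1L]))
      if (rel < tol) { converged <- TRUE; break }
    }
    alpha <- min(max(es$gamma1_sum / es$n_total, 1e-6), 0.5)
    Tg <- .update_T(es$xi, d, alpha, Tg)
    em <- es$counts / pmax(rowSums(es$counts), .Machine$double.eps)
    # freeze the two diagnostic-crossover entries, renormalize the rest
    e_new <- em
    e_new[1, 2] <- frozen[1]
    e_new[1, -2] <- em[1, -2] / sum(em[1, -2]) * (1 - frozen[1])
    e_new[2, 1] <- frozen[2]
    e_new[2, -1] <- em[2, -1] / sum(em[2, -1]) * (1 - frozen[2])
    e <- pmax(e_new, 1e-12)
    e <- e / rowSums(e)
  }
  structure(list(alpha = alpha, T = Tg, emission = e, epsilon = epsilon,
                 loglik = trace, converged = converged, freq = freq,
                 frozen = frozen),
            class = "hmm_params")
}

.update_T <- function(xi, d, alpha, t_cur) {
  qfun <- function(logT) {
    q <- pmin(pmax(1 - exp(-exp(logT) * d), 1e-12), 1 - 1e-12)
    a01 <- alpha * q; a10 <- (1 - alpha) * q
    sum(xi[, 1] * log1p(-a01) + xi[, 2] * log(a01) +
        xi[, 3] * log(a10) + xi[, 4] * log1p(-a10))
  }
  opt <- stats::optimize(qfun, interval = log(c(1, 1e5)), maximum = TRUE,
                         tol = 1e-4)
  # keep the previous value if the search did not improve on it
  if (qfun(log(t_cur)) > opt$objective) t_cur else exp(opt$maximum)
}

#' @export
print.hmm_params <- function(x, ...) {
  cat("<hmm_params> alpha =", signif(x$alpha, 4),
      " T =", signif(x$T, 5), "generations\n")
  cat("  log-likelihood:", signif(utils::tail(x$loglik, 1), 8),
      sprintf("(%d EM iterations, %s)\n", length(x$loglik),
              if (x$converged) "converged" else "max_iter reached"))
  print(round(x$emission, 5))
  invisible(x)
}

#' Decode introgressed segments
#'
#' Runs the Viterbi algorithm per test haplotype under the fitted
#' parameters; each maximal run of the hidden archaic state becomes a
#' segment.  Segment boundaries are placed at the midpoint between the two
#' SNPs flanking the state switch (ties broken toward the shorter archaic
#' segment); runs touching the first/last site end at that site.  The mean
#' forward-backward posterior of the archaic state over the run is
#' attached.
#'
#' @param obs observation matrix ([observation_matrix()]) or `NULL`.
#' @param panel a polarized [site_panel()] with genetic positions.
#' @param params fitted `"hmm_params"` from [em_fit()].
#' @return segment data frame: `chrom`, `start`, `end` (bp, 0-based
#'   half-open), `hap`, `state`, `mean_posterior`, `n_snps`.
#' @export
decode_segments <- function(obs = NULL, panel, params) {
  if (is.null(panel$gpos)) panel <- attach_genetic_map(panel, NULL)
  if (is.null(obs)) obs <- observation_matrix(panel)
  d <- pmax(diff(panel$gpos), 1e-9)
  pos <- panel$pos
  n <- length(pos)
  out <- list()
  for (j in seq_len(ncol(obs))) {
    path <- .hmm_viterbi(obs[, j], d, params$emission, params$alpha,
                         params$T)
    if (!any(path == 1L)) next
    post <- .hmm_posterior(obs[, j], d, params$emission, params$alpha,
                           params$T)$gamma[, 2]
    r <- rle(path)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    arch <- which(r$values == 1L)
    for (k in arch) {
      i1 <- starts[k]; i2 <- ends[k]
      s <- if (i1 == 1L) pos[1L] else
        floor((pos[i1 - 1L] + pos[i1]) / 2) + 1L
      e <- if (i2 == n) pos[n] + 1L else
        ceiling((pos[i2] + pos[i2 + 1L]) / 2)
      out[[length(out) + 1L]] <- data.frame(
        chrom = panel$chrom, start = as.integer(s), end = as.integer(e),
        hap = colnames(obs)[j], state = "archaic",
        mean_posterior = mean(post[i1:i2]), n_snps = i2 - i1 + 1L,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), hap = character(),
                      state = character(), mean_posterior = numeric(),
                      n_snps = integer(), stringsAsFactors = FALSE))
  seg <- do.call(rbind, out)
  seg <- seg[order(seg$hap, seg$start), ]
  rownames(seg) <- NULL
  validate_segments(seg)
  seg
}

#' Scan a panel for archaic introgressed segments
#'
#' One-call interface around [observation_matrix()], [em_fit()] and
#' [decode_segments()].  Returns a fitted-scan object with the usual
#' accessor methods (`print`, `summary`, `coef`, `logLik`, `plot`).
#'
#' @inheritParams em_fit
#' @param map optional [genetic_map()] attached before fitting.
#' @return an object of class `"archaic_scan"` with elements `params`
#'   (fitted `"hmm_params"`), `segments` (decoded segment table), `freq`,
#'   `n_hap`, `genome_bp`, and `called_fraction`.
#' @examples
#' cfg <- scenario_config(chrom_len = 2e6, n_test = 4, n_african = 8,
#'                        waves = list(list(lineage = "NEA", t = 2000,
#'                                          m = 0.03)), seed = 7)
#' sim <- simulate_panel(cfg)
#' scan <- seek(sim$panel)
#' scan
#' @export
seek <- function(panel, map = NULL, alpha0 = 0.02, t0 = 2000,
                 epsilon = 0.99, tol = 1e-5, max_iter = 200L) {
  if (!panel$polarized) panel <- polarize(panel)
  if (!is.null(map) || is.null(panel$gpos))
    panel <- attach_genetic_map(panel, map)
  obs <- observation_matrix(panel)
  params <- em_fit(obs, panel, alpha0 = alpha0, t0 = t0,
                   epsilon = epsilon, tol = tol, max_iter = max_iter)
  seg <- decode_segments(obs, panel, params)
  genome_bp <- panel$pos[length(panel$pos)] + 1L - panel$pos[1L]
  called <- if (nrow(seg)) sum(seg$end - seg$start) else 0
  structure(list(params = params, segments = seg,
                 freq = params$freq, n_hap = ncol(obs),
                 genome_bp = genome_bp,
                 called_fraction = called / (genome_bp * ncol(obs))),
            class = "archaic_scan")
}

#' @export
print.archaic_scan <- function(x, ...) {
  cat("Archaic introgression scan\n")
  cat(sprintf("  %d test haplotypes, %.3g Mb scanned\n", x$n_hap,
              x$genome_bp / 1e6))
  cat(sprintf("  fitted alpha = %.4g, T = %.0f generations\n",
              x$params$alpha, x$params$T))
  cat(sprintf("  %d segments decoded (%.2f%% of haplotype-bp archaic)\n",
              nrow(x$segments), 100 * x$called_fraction))
  invisible(x)
}

#' @export
summary.archaic_scan <- function(object, ...) {
  seg <- object$segments
  res <- list(alpha = object$params$alpha, T = object$params$T,
              emission = object$params$emission,
              n_segments = nrow(seg),
              called_fraction = object$called_fraction,
              length_summary = if (nrow(seg))
                summary(seg$end - seg$start) else NULL,
              loglik = utils::tail(object$params$loglik, 1),
              n_iter = length(object$params$loglik),
              converged = object$params$converged)
  class(res) <- "summary.archaic_scan"
  res
}

#' @export
print.summary.archaic_scan <- function(x, ...) {
  cat("Archaic introgression scan - summary\n")
  cat(sprintf("  alpha = %.4g  T = %.0f gens  logLik = %.4f (%d iter%s)\n",
              x$alpha, x$T, x$loglik, x$n_iter,
              if (x$converged) ", converged" else ""))
  cat(sprintf("  segments: %d  (%.3f%% of haplotype-bp)\n", x$n_segments,
              100 * x$called_fraction))
  if (!is.null(x$length_summary)) {
    cat("  segment length (bp):\n")
    print(x$length_summary)
  }
  cat("  emission matrix:\n")
  print(round(x$emission, 5))
  invisible(x)
}

#' @export
coef.archaic_scan <- function(object, ...)
  c(alpha = object$params$alpha, T = object$params$T)

#' @export
logLik.archaic_scan <- function(object, ...) {
  ll <- utils::tail(object$params$loglik, 1)
  # alpha, T and the six free emission entries
  attr(ll, "df") <- 8
  class(ll) <- "logLik"
  ll
}

#' @export
plot.archaic_scan <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(x$params$loglik, type = "b", xlab = "EM iteration",
                 ylab = "log-likelihood", main = "EM trace", ...)
  if (nrow(x$segments))
    graphics::hist(log10(x$segments$end - x$segments$start), breaks = 30,
                   xlab = "log10 segment length (bp)", main = "Segments")
  invisible(x)
}
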