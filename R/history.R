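#' Convert matched segments into a tract-length sample
#'
#' Drops segments shorter than `min_bp` (strictly; 15 kb by default, the
#' length below which boundary errors dominate) and converts the retained
#' lengths to Morgans with the genetic map.  The resulting sample is the
#' input of the wave-model fit; the truncation bound is carried along so
#' the fit can correct for it.
#'
#' @param segments segment table, already restricted to one matched
#'   lineage.
#' @param map a [genetic_map()] or `NULL` for the 1 cM/Mb fallback.
#' @param min_bp minimum retained physical length (bp), strict lower
#'   bound: a segment of exactly `min_bp` is kept.
#' @return list of class `"tract_sample"`: `morgans`, `bp`, `hap`,
#'   `trunc_morgans` (the truncation bound converted at each segment's own
#'   local rate is approximated by the map-converted bound), `n`.
#' @export
filter_and_convert <- function(segments, map = NULL, min_bp = 15000) {
  keep <- (segments$end - segments$start) >= min_bp
  seg <- segments[keep, , drop = FALSE]
  if (!nrow(seg)) stop("insufficient tracts: none of length >= ", min_bp)
  g1 <- interpolate_cm(map, seg$start) / 100
  g2 <- interpolate_cm(map, seg$end) / 100
  morgans <- g2 - g1
  # truncation bound in Morgans at the sample's average local rate
  rate <- sum(morgans) / sum(seg$end - seg$start)
  structure(list(morgans = morgans, bp = seg$end - seg$start,
                 hap = seg$hap, trunc_morgans = min_bp * rate,
                 n = nrow(seg)),
            class = "tract_sample")
}

#' @export
print.tract_sample <- function(x, ...) {
  cat("<tract_sample>", x$n, "tracts;",
      sprintf("mean %.3g Morgans (%.1f kb); truncation %.3g Morgans\n",
              mean(x$morgans), mean(x$bp) / 1000, x$trunc_morgans))
  invisible(x)
}

# EM for a K-component exponential mixture on shifted lengths y = x - c.
.exp_mix_em <- function(y, K, tol = 1e-6, max_iter = 500L,
                        restarts = 10L, seed = 1L) {
  n <- length(y)
  best <- NULL
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  for (r in seq_len(restarts)) {
    if (r == 1L) {
      qs <- stats::quantile(y, probs = seq(0.2, 0.95,
                                           length.out = K) / 1.2)
      u <- 1 / pmax(qs, min(y[y > 0], 1e-12))
    } else {
      u <- 1 / (mean(y) * stats::runif(K, 0.2, 3))
    }
    w <- rep(1 / K, K)
    ll_old <- -Inf; ll_tr <- numeric(0)
    for (it in seq_len(max_iter)) {
      dens <- vapply(seq_len(K), function(k)
        w[k] * stats::dexp(y, u[k]), numeric(n))
      dens <- matrix(dens, nrow = n)
      tot <- rowSums(dens)
      tot[tot <= 0] <- .Machine$double.xmin
      ll <- sum(log(tot))
      ll_tr <- c(ll_tr, ll)
      z <- dens / tot
      nk <- colSums(z)
      w <- nk / n
      u <- nk / pmax(colSums(z * y), .Machine$double.xmin)
      if (is.finite(ll_old) && abs(ll - ll_old) <
          tol * max(1, abs(ll_old))) break
      ll_old <- ll
    }
    if (is.null(best) || ll > best$loglik)
      best <- list(rates = u, weights = w, loglik = ll, trace = ll_tr,
                   iter = it)
  }
  if (is.null(best) || !is.finite(best$loglik))
    stop("exponential-mixture EM failed to converge; diagnostics: n = ",
         n, ", K = ", K)
  o <- order(best$rates, decreasing = TRUE)  # high rate = old wave first
  best$rates <- best$rates[o]; best$weights <- best$weights[o]
  best
}

#' Fit a K-wave introgression model to tract lengths
#'
#' Under pulse admixture, tracts contributed by a wave of age `t`
#' generations have exponentially distributed genetic lengths with rate
#' close to `t` per Morgan; a K-wave history yields a K-component
#' exponential mixture.  The fit handles the left truncation of the
#' sample at `trunc_morgans` analytically: a truncated exponential mixture
#' is again an exponential mixture in the shifted lengths, with component
#' weights damped by `exp(-u_k c)`; the fit runs EM on the shifted lengths
#' and un-damps the weights afterwards.  Wave times apply the standard
#' small-proportion correction `t_k = u_k / (1 - alpha_total)` and wave
#' proportions split the genome-wide introgressed fraction in proportion
#' to each component's length mass (`w_k / u_k`).
#'
#' @param sample a `"tract_sample"` from [filter_and_convert()].
#' @param K number of waves (>= 1); requires `n >= 10 K` tracts.
#' @param alpha_total genome-wide introgressed fraction for the lineage
#'   (used for the time correction and to scale wave proportions); when
#'   `NULL` the proportions are reported relative to an unscaled total of
#'   `sum(m_k) = NA` and no correction is applied.
#' @param tol,max_iter,restarts,seed EM controls (fixed-seed restarts).
#' @return an object of class `"wave_model"`: `K`, `t` (generations,
#'   oldest first), `m` (proportions), `rates`, `weights`, `loglik`,
#'   `n`, `alpha_total`.
#' @export
fit_waves <- function(sample, K = 1L, alpha_total = NULL, tol = 1e-6,
                      max_iter = 500L, restarts = 10L, seed = 1L) {
  stopifnot(inherits(sample, "tract_sample"), K >= 1L)
  if (sample$n < 10L * K)
    stop("need at least ", 10L * K, " tracts to fit K = ", K)
  y <- pmax(sample$morgans - sample$trunc_morgans, 0)
  if (K == 1L) {
    u <- 1 / mean(y)  # closed-form exponential MLE
    fit <- list(rates = u, weights = 1,
                loglik = sum(stats::dexp(y, u, log = TRUE)), iter = 0L)
  } else {
    fit <- .exp_mix_em(y, K, tol = tol, max_iter = max_iter,
                       restarts = restarts, seed = seed)
  }
  # undo the truncation damping of the weights
  w_raw <- fit$weights * exp(fit$rates * sample$trunc_morgans)
  w <- w_raw / sum(w_raw)
  corr <- if (is.null(alpha_total)) 1 else 1 - alpha_total
  t_gen <- fit$rates / corr
  mass <- w / fit$rates
  m <- if (is.null(alpha_total)) rep(NA_real_, K) else
    alpha_total * mass / sum(mass)
  structure(list(K = K, t = t_gen, m = m, rates = fit$rates,
                 weights = w, loglik = fit$loglik, n = sample$n,
                 alpha_total = alpha_total),
            class = "wave_model")
}

#' @export
print.wave_model <- function(x, ...) {
  cat("Introgression wave model: K =", x$K, "wave(s),", x$n, "tracts\n")
  for (k in seq_len(x$K))
    cat(sprintf("  wave %d: t = %.0f generations (%.1f kya at 30 y), m = %s\n",
                k, x$t[k], generations_to_kya(x$t[k]),
                if (is.na(x$m[k])) "unscaled" else
                  sprintf("%.3f%%", 100 * x$m[k])))
  cat(sprintf("  log-likelihood: %.4f\n", x$loglik))
  invisible(x)
}

#' @export
summary.wave_model <- function(object, ...) {
  d <- data.frame(wave = seq_len(object$K), t_generations = object$t,
                  t_kya = generations_to_kya(object$t),
                  proportion = object$m, rate = object$rates,
                  weight = object$weights)
  cat("Introgression wave model (oldest wave first)\n")
  print(d, row.names = FALSE)
  cat(sprintf("n = %d tracts, logLik = %.4f, total proportion = %s\n",
              object$n, object$loglik,
              if (is.null(object$alpha_total)) "unscaled" else
                sprintf("%.3f%%", 100 * object$alpha_total)))
  invisible(d)
}

#' @export
coef.wave_model <- function(object, ...) {
  out <- c(rbind(object$t, object$m))
  names(out) <- paste0(rep(c("t", "m"), object$K),
                       rep(seq_len(object$K), each = 2))
  out
}

#' @export
logLik.wave_model <- function(object, ...) {
  ll <- object$loglik
  attr(ll, "df") <- 2 * object$K - 1
  class(ll) <- "logLik"
  ll
}

#' Select the number of introgression waves by sequential LRT
#'
#' Fits K = 1, 2, ... up to `K_max` and tests K against K + 1 with a
#' likelihood-ratio test (2 dLogL against chi-squared with 2 degrees of
#' freedom: one extra time, one extra proportion).  Returns the smallest K
#' that is not rejected in favour of K + 1.  A guard requires at least
#' `10 (K + 1)` tracts before a larger model is even attempted.
#'
#' @inheritParams fit_waves
#' @param K_max largest number of waves considered.
#' @param alpha_lrt significance level of each LRT.
#' @return the selected `"wave_model"`, with the LRT table attached as
#'   attribute `"lrt"`.
#' @export
select_waves <- function(sample, K_max = 3L, alpha_lrt = 0.05,
                         alpha_total = NULL, seed = 1L) {
  crit <- stats::qchisq(1 - alpha_lrt, df = 2)
  fit <- fit_waves(sample, 1L, alpha_total = alpha_total, seed = seed)
  lrt <- data.frame(K0 = integer(), K1 = integer(), stat = numeric(),
                    p = numeric())
  K <- 1L
  while (K < K_max && sample$n >= 10L * (K + 1L)) {
    fit1 <- tryCatch(fit_waves(sample, K + 1L, alpha_total = alpha_total,
                               seed = seed),
                     error = function(e) NULL)
    if (is.null(fit1)) break
    stat <- 2 * (fit1$loglik - fit$loglik)
    lrt <- rbind(lrt, data.frame(K0 = K, K1 = K + 1L, stat = stat,
                                 p = stats::pchisq(stat, 2,
                                                   lower.tail = FALSE)))
    if (stat <= crit) break
    fit <- fit1
    K <- K + 1L
  }
  attr(fit, "lrt") <- lrt
  fit
}

#' Bootstrap confidence intervals and wave-number support
#'
#' Resamples tracts with replacement `B` times and refits, including the
#' LRT selection of K, reporting the fraction of resamples supporting each
#' K (the support ratio) and 2.5/97.5 percentile intervals of the wave
#' times and proportions among resamples whose selected K matches the
#' fitted model.
#'
#' @inheritParams select_waves
#' @param model the fitted `"wave_model"` to bootstrap around.
#' @param B number of resamples (> 0).
#' @param seed integer seed.
#' @return list of class `"wave_bootstrap"`: `support` (named vector over
#'   K), `ci_t`, `ci_m` (2 x K matrices), `B`.
#' @export
bootstrap_waves <- function(sample, model, B = 100L, alpha_lrt = 0.05,
                            K_max = 3L, seed = 1L) {
  if (B <= 0) stop("B must be positive")
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  Ks <- integer(B)
  ts <- vector("list", B); ms <- vector("list", B)
  for (b in seq_len(B)) {
    i <- sample.int(sample$n, replace = TRUE)
    sb <- structure(list(morgans = sample$morgans[i], bp = sample$bp[i],
                         hap = sample$hap[i],
                         trunc_morgans = sample$trunc_morgans,
                         n = sample$n),
                    class = "tract_sample")
    fb <- tryCatch(select_waves(sb, K_max = K_max, alpha_lrt = alpha_lrt,
                                alpha_total = model$alpha_total,
                                seed = seed + b),
                   error = function(e) NULL)
    if (is.null(fb)) { Ks[b] <- NA; next }
    Ks[b] <- fb$K
    if (fb$K == model$K) { ts[[b]] <- fb$t; ms[[b]] <- fb$m }
  }
  support <- table(factor(Ks, levels = seq_len(K_max))) / sum(!is.na(Ks))
  tmat <- do.call(rbind, ts); mmat <- do.call(rbind, ms)
  qs <- function(m) if (is.null(m)) NULL else
    apply(m, 2, stats::quantile, probs = c(0.025, 0.975), na.rm = TRUE)
  structure(list(support = c(support), ci_t = qs(tmat), ci_m = qs(mmat),
                 B = B),
            class = "wave_bootstrap")
}

#' @export
print.wave_bootstrap <- function(x, ...) {
  cat("<wave_bootstrap> B =", x$B, "\n  support ratio:",
      paste(sprintf("K=%s: %.2f", names(x$support), x$support),
            collapse = "  "), "\n")
  if (!is.null(x$ci_t)) {
    cat("  95% CI, wave times (generations):\n")
    print(round(x$ci_t, 1))
  }
  invisible(x)
}

#' Convert generations to thousands of years
#'
#' @param t time in generations.
#' @param gen_years years per generation (30).
#' @return time in kya.
#' @examples
#' generations_to_kya(2000)  # 60 kya
#' @export
generations_to_kya <- function(t, gen_years = 30) t * gen_years / 1000

#' Reconstruct the introgression history of a lineage
#'
#' End-to-end history step: restricts matched segments to one lineage
#' class (segments labelled ILS or false positive are excluded), filters
#' short tracts, selects the number of waves by LRT and screens
#' extremely small unstable waves — a wave with proportion below 0.5% is
#' dropped (and the model refitted with one wave fewer) when fewer than
#' half of the bootstrap resamples support the selected K, mirroring the
#' observation that spurious extra events carry small and unstable
#' proportions.
#'
#' @param matched matched segment table from [match_segments()].
#' @param lineage label(s) to keep (e.g. `"NEA"`), or `"archaic"` to pool
#'   every archaic-class label.
#' @param genome_bp genome length per haplotype (for the introgressed
#'   fraction).
#' @param n_hap number of test haplotypes scanned.
#' @param map optional [genetic_map()].
#' @param min_bp tract-length filter (bp).
#' @param K_max,alpha_lrt selection controls.
#' @param B_screen bootstrap resamples used by the small-wave screen
#'   (0 disables screening).
#' @param seed integer seed.
#' @return the selected `"wave_model"`, with attributes `"screened"`
#'   (logical) and `"bootstrap"` when screening ran.
#' @export
reconstruct_history <- function(matched, lineage, genome_bp, n_hap,
                                map = NULL, min_bp = 15000, K_max = 3L,
                                alpha_lrt = 0.05, B_screen = 50L,
                                seed = 1L) {
  sel <- if (identical(lineage, "archaic"))
    matched$lineage_class == "archaic"
  else matched$label %in% lineage
  seg <- matched[sel, , drop = FALSE]
  if (!nrow(seg)) stop("no segments matched to lineage ",
                       paste(lineage, collapse = "/"))
  alpha_total <- sum(seg$end - seg$start) / (genome_bp * n_hap)
  sm <- filter_and_convert(seg, map = map, min_bp = min_bp)
  fit <- select_waves(sm, K_max = K_max, alpha_lrt = alpha_lrt,
                      alpha_total = alpha_total, seed = seed)
  screened <- FALSE; bs <- NULL
  while (fit$K > 1L && B_screen > 0L && any(fit$m < 0.005)) {
    bs <- bootstrap_waves(sm, fit, B = B_screen, alpha_lrt = alpha_lrt,
                          K_max = K_max, seed = seed)
    if (bs$support[fit$K] < 0.5) {
      fit <- fit_waves(sm, fit$K - 1L, alpha_total = alpha_total,
                       seed = seed)
      screened <- TRUE
    } else break
  }
  attr(fit, "screened") <- screened
  attr(fit, "bootstrap") <- bs
  fit
}
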