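#' Two-factor repeated-measures ANOVA with sphericity handling
#'
#' Both factors are within-subject (every species carries all
#' predictor x algorithm cells). Sums of squares are computed from cell and
#' marginal means; because the design is complete and balanced, Type I and
#' Type III sums of squares coincide. Each within-subject effect is tested
#' against its own subject-interaction error stratum. Per effect, Mauchly's
#' sphericity test (chi-square approximation with the small-sample
#' correction factor) is run on the covariance of orthonormal contrast
#' scores, and the Greenhouse-Geisser epsilon
#' `eps = (sum lambda)^2 / (q * sum lambda^2)` (eigenvalues `lambda` of that
#' covariance, `q` = contrast dimension) shrinks the degrees of freedom.
#' The reported `df` are GG-corrected when Mauchly rejects at `alpha`;
#' uncorrected otherwise. A 2-level effect has a single contrast, so
#' `W = 1` and `eps = 1` exactly and no correction can apply.
#'
#' @param table long-format data.frame with columns `species`, `predictor`,
#'   `algorithm` and the response named by `response`.
#' @param response response column name.
#' @param alpha Mauchly test level governing when GG correction is applied.
#' @return object of class `rm_anova`: `effects` data.frame (one row per
#'   effect: SS, df, MS, F, p, mauchly_W, mauchly_p, gg_eps, df_gg,
#'   df_err_gg, p_gg, df_reported, p_reported), plus `strata` (the error
#'   SS table) and the design sizes.
#' @export
rm_anova <- function(table, response = "TSS", alpha = 0.05) {
  need <- c("species", "predictor", "algorithm", response)
  if (!all(need %in% names(table)))
    stop("table must have columns ", paste(need, collapse = ", "))
  tab <- table[stats::complete.cases(table[need]), need]
  subj <- sort(unique(tab$species))
  A <- sort(unique(tab$predictor)); B <- sort(unique(tab$algorithm))
  n <- length(subj); a <- length(A); b <- length(B)
  if (nrow(tab) != n * a * b)
    stop("design is not complete and balanced: expected ", n * a * b,
         " rows, got ", nrow(tab))
  Y <- array(NA_real_, c(n, a, b))
  Y[cbind(match(tab$species, subj), match(tab$predictor, A),
          match(tab$algorithm, B))] <- tab[[response]]
  if (anyNA(Y)) stop("missing cells in the design")

  gm <- mean(Y)
  m_s <- apply(Y, 1, mean); m_a <- apply(Y, 2, mean); m_b <- apply(Y, 3, mean)
  m_sa <- apply(Y, c(1, 2), mean); m_sb <- apply(Y, c(1, 3), mean)
  m_ab <- apply(Y, c(2, 3), mean)

  SS_A <- n * b * sum((m_a - gm)^2)
  SS_B <- n * a * sum((m_b - gm)^2)
  SS_AB <- n * sum((m_ab - outer(m_a, rep(1, b)) -
                      outer(rep(1, a), m_b) + gm)^2)
  SS_S <- a * b * sum((m_s - gm)^2)
  SS_AS <- b * sum((m_sa - outer(m_s, rep(1, a)) -
                      outer(rep(1, n), m_a) + gm)^2)
  SS_BS <- a * sum((m_sb - outer(m_s, rep(1, b)) -
                      outer(rep(1, n), m_b) + gm)^2)
  SS_T <- sum((Y - gm)^2)
  SS_ABS <- SS_T - SS_A - SS_B - SS_AB - SS_S - SS_AS - SS_BS

  ortho <- function(k) {
    M <- stats::contr.helmert(k)
    qr.Q(qr(M))
  }
  MA <- ortho(a); MB <- ortho(b)
  # per-subject response matrices for each effect's contrast space
  YA <- apply(Y, c(1, 2), mean)                      # n x a (means over b)
  YB <- apply(Y, c(1, 3), mean)
  Ycell <- matrix(aperm(Y, c(1, 3, 2)), nrow = n)    # columns: A slow, B fast
  MAB <- kronecker(MA, MB)

  sphericity <- function(Z) {
    q <- ncol(Z)
    if (q == 1L)
      return(list(W = 1, p = NA_real_, eps = 1))
    S <- stats::cov(Z)
    lam <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    lam <- pmax(lam, 0)
    W <- if (all(lam > 0)) prod(lam) / (mean(lam)^q) else 0
    eps <- sum(lam)^2 / (q * sum(lam^2))
    p <- if (n - 1 > q && W > 0) {
      df <- q * (q + 1) / 2 - 1
      d <- 1 - (2 * q^2 + q + 2) / (6 * q * (n - 1))
      stats::pchisq(-(n - 1) * d * log(W), df, lower.tail = FALSE)
    } else NA_real_
    list(W = W, p = p, eps = eps)
  }
  sA <- sphericity(YA %*% MA)
  sB <- sphericity(YB %*% MB)
  sAB <- sphericity(Ycell %*% MAB)

  mk <- function(name, SS, df1, SS_err, df2, sph) {
    MS <- SS / df1; MS_err <- SS_err / df2
    F <- MS / MS_err
    p <- stats::pf(F, df1, df2, lower.tail = FALSE)
    p_gg <- stats::pf(F, sph$eps * df1, sph$eps * df2, lower.tail = FALSE)
    corrected <- !is.na(sph$p) && sph$p < alpha
    data.frame(effect = name, SS = SS, df = df1, MS = MS, F = F, p = p,
               SS_error = SS_err, df_error = df2,
               mauchly_W = sph$W, mauchly_p = sph$p, gg_eps = sph$eps,
               df_gg = sph$eps * df1, df_err_gg = sph$eps * df2, p_gg = p_gg,
               df_reported = if (corrected) sph$eps * df1 else df1,
               p_reported = if (corrected) p_gg else p)
  }
  eff <- rbind(
    mk("Predictor", SS_A, a - 1, SS_AS, (a - 1) * (n - 1), sA),
    mk("Algorithm", SS_B, b - 1, SS_BS, (b - 1) * (n - 1), sB),
    mk("Predictor:Algorithm", SS_AB, (a - 1) * (b - 1), SS_ABS,
       (a - 1) * (b - 1) * (n - 1), sAB))
  structure(list(effects = eff,
                 strata = data.frame(
                   stratum = c("Subject", "Subject:Predictor",
                               "Subject:Algorithm",
                               "Subject:Predictor:Algorithm", "Total"),
                   SS = c(SS_S, SS_AS, SS_BS, SS_ABS, SS_T)),
                 n_subjects = n, a = a, b = b, response = response,
                 alpha = alpha),
            class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("Repeated-measures ANOVA on %s (%d subjects, %d x %d within design)\n",
              x$response, x$n_subjects, x$a, x$b))
  e <- x$effects
  out <- data.frame(Effect = e$effect, SS = signif(e$SS, 4),
                    Df = signif(e$df_reported, 4), MS = signif(e$MS, 4),
                    F = signif(e$F, 4), p = signif(e$p_reported, 3),
                    GG.eps = signif(e$gg_eps, 3))
  print(out, row.names = FALSE)
  invisible(x)
}

#' Summarize pairwise map correlations
#'
#' Mean and normal-approximation 95% confidence interval of Kendall tau
#' across species, per comparison cell: predictor pairs within each
#' algorithm, and algorithm pairs within each predictor set.
#'
#' @param taus data.frame with columns `species`, `type` (`"predictor_pair"`
#'   or `"algorithm_pair"`), `group` (the held-fixed level), `pair`, `tau`.
#' @return data.frame with per-cell `n`, `mean`, `sd`, `ci_lo`, `ci_hi`;
#'   cells with fewer than 2 species are dropped with a warning.
#' @export
summarize_pairwise_tau <- function(taus) {
  sp <- split(taus, interaction(taus$type, taus$group, taus$pair, drop = TRUE))
  keep <- vapply(sp, nrow, integer(1)) >= 2L
  if (any(!keep))
    warning(sum(!keep), " comparison cell(s) with < 2 species omitted")
  out <- do.call(rbind, lapply(sp[keep], function(d) {
    m <- mean(d$tau); s <- stats::sd(d$tau); n <- nrow(d)
    data.frame(type = d$type[1], group = d$group[1], pair = d$pair[1],
               n = n, mean = m, sd = s,
               ci_lo = m - 1.96 * s / sqrt(n),
               ci_hi = m + 1.96 * s / sqrt(n))
  }))
  if (is.null(out))
    return(data.frame(type = character(0), group = character(0),
                      pair = character(0), n = integer(0), mean = numeric(0),
                      sd = numeric(0), ci_lo = numeric(0), ci_hi = numeric(0)))
  rownames(out) <- NULL
  out[order(out$type, out$group, out$pair), ]
}

#' Arcsine transform for TSS
#'
#' Default is `asin(x)` on the raw statistic, which is well defined on the
#' whole TSS range `[-1, 1]` and strictly increasing. The classical
#' proportion transform `asin(sqrt(x))` (negatives clipped to 0) is
#' available behind a flag.
#'
#' @param x values in `[-1, 1]`.
#' @param sqrt_variant use `asin(sqrt(pmax(x, 0)))` instead.
#' @return transformed values.
#' @export
arcsine_tss <- function(x, sqrt_variant = FALSE) {
  if (any(abs(x) > 1, na.rm = TRUE)) stop("TSS values must lie in [-1, 1]")
  if (sqrt_variant) asin(sqrt(pmax(x, 0))) else asin(x)
}
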