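#' Kal's Z-test for two unreplicated libraries
#'
#' Compares a tag proportion between two libraries with the pooled-variance
#' normal statistic
#' `z = (p1 - p2) / sqrt(p0 (1 - p0) (1/N1 + 1/N2))`,
#' `p0 = (x1 + x2) / (N1 + N2)`.  Two-sided p-value from the standard
#' normal; `x1 = x2 = 0` gives `z = 0`, `p = 1` by convention.
#'
#' @param x1,x2 Counts in library 1 and 2.
#' @param N1,N2 Library sizes (total quantified reads).
#' @return A `kal_test` list: `p1`, `p2`, `p0`, `z`, `p_value`.
#' @export
kal_z_test <- function(x1, N1, x2, N2) {
  stopifnot(N1 >= 1, N2 >= 1, x1 >= 0, x2 >= 0)
  if (x1 > N1 || x2 > N2) stop("count exceeds library size")
  p1 <- x1 / N1
  p2 <- x2 / N2
  p0 <- (x1 + x2) / (N1 + N2)
  v <- p0 * (1 - p0) * (1 / N1 + 1 / N2)
  z <- if (v > 0) (p1 - p2) / sqrt(v) else 0
  p <- if (v > 0) 2 * pnorm(-abs(z)) else 1
  structure(list(p1 = p1, p2 = p2, p0 = p0, z = z, p_value = p),
            class = "kal_test")
}

# vectorized z and p for simulation studies
kal_z_vec <- function(x1, N1, x2, N2) {
  p1 <- x1 / N1; p2 <- x2 / N2
  p0 <- (x1 + x2) / (N1 + N2)
  v <- p0 * (1 - p0) * (1 / N1 + 1 / N2)
  z <- ifelse(v > 0, (p1 - p2) / sqrt(pmax(v, .Machine$double.xmin)), 0)
  list(z = z, p = ifelse(v > 0, 2 * pnorm(-abs(z)), 1))
}

# weighted per-group proportion estimate with between-replicate
# overdispersion (method of moments, floored at zero); returns the
# estimate, its variance, the overdispersion-attributable share of that
# variance (the only part whose estimation consumes degrees of freedom;
# the binomial part is known given N) and the replicate count
baggerly_group <- function(x, N) {
  K <- length(x)
  p <- x / N
  ptilde <- sum(x) / sum(N)
  # variance floor keeps weights finite for all-zero groups
  pfloor <- max(ptilde, 0.5 / sum(N))
  sigma2 <- 0
  w <- N
  vbin <- rep(0, K)
  for (i in 1:3) {
    vbin <- pmax(ptilde * (1 - ptilde), pfloor * (1 - pfloor)) / N
    sigma2 <- max(0, var(p) - mean(vbin))
    w <- 1 / (vbin + sigma2)
    ptilde <- sum(w * p) / sum(w)
  }
  v <- 1 / sum(w)
  v_est <- v * sigma2 / (sigma2 + mean(vbin))
  list(p = ptilde, v = v, v_est = v_est, K = K)
}

#' Baggerly-style weighted proportion test for replicated groups
#'
#' Weighted t-type test on tag proportions combining the binomial
#' within-library variance `p(1-p)/N_s` with a method-of-moments
#' between-replicate overdispersion (floored at zero).  The statistic is
#' `tw = (p1 - p2) / sqrt(V1 + V2)` with Satterthwaite degrees of freedom;
#' with zero overdispersion and equal library sizes the statistic reduces
#' to the pooled two-proportion z statistic (the p-value stays referred to
#' the heavier-tailed t, which protects against the noise of the
#' overdispersion estimate at few replicates).
#'
#' @param x1,x2 Integer vectors of per-replicate counts for group 1 and 2.
#' @param N1,N2 Integer vectors of per-replicate library sizes.
#' @return A `baggerly_test` list: `p1`, `p2`, `v1`, `v2`, `tw`, `df`,
#'   `p_value`.
#' @export
baggerly_test <- function(x1, N1, x2, N2) {
  if (length(x1) < 2L || length(x2) < 2L)
    stop("baggerly_test needs >= 2 replicates per group; ",
         "use kal_z_test for unreplicated samples")
  stopifnot(length(x1) == length(N1), length(x2) == length(N2),
            all(N1 >= 1), all(N2 >= 1), all(x1 >= 0), all(x2 >= 0))
  if (any(x1 > N1) || any(x2 > N2)) stop("count exceeds library size")
  if (sum(x1) + sum(x2) == 0) {
    return(structure(list(p1 = 0, p2 = 0, v1 = 0, v2 = 0, tw = 0,
                          df = length(x1) + length(x2) - 2, p_value = 1),
                     class = "baggerly_test"))
  }
  g1 <- baggerly_group(x1, N1)
  g2 <- baggerly_group(x2, N2)
  vsum <- g1$v + g2$v
  tw <- if (vsum > 0) (g1$p - g2$p) / sqrt(vsum) else 0
  # Satterthwaite df over the weighted group variances; the heavy t tails
  # at few replicates guard against the noise of the moment-based
  # overdispersion estimate
  denom <- g1$v^2 / (g1$K - 1) + g2$v^2 / (g2$K - 1)
  df <- if (denom > 0) max(vsum^2 / denom, 1) else g1$K + g2$K - 2
  p <- if (tw == 0) 1 else 2 * pt(-abs(tw), df)
  structure(list(p1 = g1$p, p2 = g2$p, v1 = g1$v, v2 = g2$v,
                 tw = tw, df = df, p_value = p),
            class = "baggerly_test")
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up q-values: `q_(i) = min_{j >= i} (m p_(j) / j)`, clipped to 1,
#' reported in the input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values.
#' @export
bh_fdr <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  if (!length(p)) return(numeric(0))
  p.adjust(p, method = "BH")
}

#' Two-condition differential repeat-expression table
#'
#' Tests each repeat family for a difference in its proportion of the
#' quantified reads between conditions.  The test is auto-selected: the
#' Baggerly weighted test when both conditions have at least two
#' replicates, otherwise Kal's Z-test on the per-condition pooled
#' libraries.  Fold change is
#' `(mean treated proportion + eps) / (mean control proportion + eps)`
#' with pseudo-proportion `eps = 0.5 / median(N)`.  Families absent from
#' every sample are excluded with a logged count.  q-values are
#' Benjamini-Hochberg across all tested families.
#'
#' @param x Matrix of quantified read counts, families x samples (with
#'   dimnames).
#' @param N Numeric vector of per-sample library sizes (total quantified
#'   reads), length `ncol(x)`.
#' @param condition Character/factor of `"control"`/`"treated"` per sample.
#' @param test `"auto"`, `"kal"` or `"baggerly"`.
#' @return A data.frame: `family`, `mean_control_prop`,
#'   `mean_treated_prop`, `fold_change`, `test`, `statistic`, `p`, `q`.
#' @export
differential_table <- function(x, N, condition,
                               test = c("auto", "kal", "baggerly")) {
  test <- match.arg(test)
  stopifnot(is.matrix(x), length(N) == ncol(x),
            length(condition) == ncol(x), all(N >= 1))
  condition <- as.character(condition)
  if (!all(condition %in% c("control", "treated")))
    stop("condition must be 'control' or 'treated'")
  ctl <- which(condition == "control")
  trt <- which(condition == "treated")
  if (!length(ctl) || !length(trt))
    stop("need at least one sample per condition")
  use_baggerly <- switch(test,
    auto = length(ctl) >= 2L && length(trt) >= 2L,
    kal = FALSE,
    baggerly = TRUE)
  if (use_baggerly && (length(ctl) < 2L || length(trt) < 2L))
    stop("baggerly requires >= 2 replicates per condition")

  present <- rowSums(x) > 0
  if (any(!present))
    message(sum(!present), " famil(y/ies) absent from all samples excluded")
  fams <- rownames(x)[present]
  eps <- 0.5 / median(N)
  rows <- lapply(fams, function(f) {
    xc <- x[f, ctl]; xt <- x[f, trt]
    mc <- mean(xc / N[ctl]); mt <- mean(xt / N[trt])
    if (use_baggerly) {
      r <- baggerly_test(xt, N[trt], xc, N[ctl])
      stat <- r$tw
    } else {
      r <- kal_z_test(sum(xt), sum(N[trt]), sum(xc), sum(N[ctl]))
      stat <- r$z
    }
    data.frame(family = f, mean_control_prop = mc, mean_treated_prop = mt,
               fold_change = (mt + eps) / (mc + eps),
               test = if (use_baggerly) "baggerly" else "kal",
               statistic = stat, p = r$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(family = character(0), mean_control_prop = numeric(0),
                      mean_treated_prop = numeric(0), fold_change = numeric(0),
                      test = character(0), statistic = numeric(0),
                      p = numeric(0), q = numeric(0), stringsAsFactors = FALSE))
  }
  out$q <- bh_fdr(out$p)
  rownames(out) <- NULL
  out
}

#' Build the count matrix for differential testing
#'
#' @param abundances Named list of `abundance_table`s (one per sample, see
#'   [quantify()]); names are sample names.
#' @param condition Character vector of `"control"`/`"treated"` per sample.
#' @return A list with `x` (families x samples count matrix), `N`
#'   (per-sample quantified totals) and `condition`.
#' @export
count_matrix <- function(abundances, condition) {
  stopifnot(length(abundances) >= 2L,
            length(condition) == length(abundances))
  fams <- abundances[[1]]$family
  x <- vapply(abundances, function(a) {
    stopifnot(identical(a$family, fams))
    as.numeric(a$count)
  }, numeric(length(fams)))
  x <- matrix(x, nrow = length(fams),
              dimnames = list(fams, names(abundances)))
  N <- vapply(abundances, function(a) as.numeric(attr(a, "n_quantified")),
              numeric(1))
  list(x = x, N = N, condition = as.character(condition))
}
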