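#' Per-metabolite fold change between two groups
#'
#' Ratio of raw (unlogged) group-mean intensities, group 2 over group 1.
#' Zero intensities are imputed to half the smallest nonzero value in the
#' table before averaging (logged).
#'
#' @param intensity metabolites x samples matrix of intensities (>= 0).
#' @param group length-`ncol` factor with exactly two levels.
#' @return named numeric vector of fold changes.
#' @export
met_fold_change <- function(intensity, group) {
  intensity <- as.matrix(intensity)
  group <- droplevels(as.factor(group))
  if (nlevels(group) != 2L) stop("exactly two groups required")
  if (any(intensity == 0)) {
    halfmin <- min(intensity[intensity > 0]) / 2
    message(sum(intensity == 0), " zero intensities imputed to ",
            signif(halfmin, 4))
    intensity[intensity == 0] <- halfmin
  }
  m1 <- rowMeans(intensity[, group == levels(group)[1], drop = FALSE])
  m2 <- rowMeans(intensity[, group == levels(group)[2], drop = FALSE])
  if (any(m1 == 0)) stop("group mean 0 after imputation")
  setNames(m2 / m1, rownames(intensity))
}

#' PLS-DA variable importance in projection (VIP)
#'
#' Fits a PLS-DA model by NIPALS on the two-group indicator after log2
#' transform and autoscaling (unit variance per metabolite), then computes
#' VIP_j = sqrt( p * sum_a[ SSY_a * (w_ja / ||w_a||)^2 ] / sum_a SSY_a )
#' where p is the number of metabolites, w_a the component-a weight vector
#' and SSY_a the Y-variance explained by component a. The mean of VIP^2
#' over metabolites is exactly 1 for every fitted model.
#'
#' @param intensity metabolites x samples matrix (> 0; zeros imputed to
#'   half-minimum before the log).
#' @param group two-level factor over samples.
#' @param n_components number of PLS components (reduced, with a warning,
#'   if it exceeds the data rank).
#' @return named numeric vector of VIP scores; metabolites with zero
#'   variance are dropped with a message.
#' @export
plsda_vip <- function(intensity, group, n_components = 2L) {
  intensity <- as.matrix(intensity)
  group <- droplevels(as.factor(group))
  if (nlevels(group) != 2L) stop("exactly two groups required")
  if (min(table(group)) < 2L) stop(">= 2 samples per group required")
  if (any(intensity == 0)) {
    intensity[intensity == 0] <- min(intensity[intensity > 0]) / 2
  }
  X <- t(log2(intensity))                       # samples x metabolites
  sds <- apply(X, 2L, sd)
  drop <- sds == 0
  if (any(drop)) {
    message("dropping ", sum(drop),
            " zero-variance metabolite(s) after autoscaling")
    X <- X[, !drop, drop = FALSE]
    sds <- sds[!drop]
  }
  X <- scale(X)
  y <- as.numeric(group == levels(group)[2])
  y <- y - mean(y)
  n_max <- min(nrow(X) - 1L, ncol(X))
  if (n_components > n_max) {
    warning("n_components reduced to the data rank (", n_max, ")")
    n_components <- n_max
  }
  p <- ncol(X)
  W <- matrix(0, p, n_components)
  ssy <- numeric(n_components)
  Xa <- X; ya <- y
  for (a in seq_len(n_components)) {
    w <- crossprod(Xa, ya)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { n_components <- a - 1L; break }
    w <- w / nw
    t_ <- Xa %*% w
    tt <- sum(t_^2)
    p_ <- crossprod(Xa, t_) / tt
    c_ <- sum(ya * t_) / tt
    Xa <- Xa - t_ %*% t(p_)
    ya <- ya - c_ * t_
    W[, a] <- w
    ssy[a] <- c_^2 * tt
  }
  if (n_components < 1L) stop("no discriminant structure; PLS-DA degenerate")
  W <- W[, seq_len(n_components), drop = FALSE]
  ssy <- ssy[seq_len(n_components)]
  vip <- sqrt(p * as.numeric(W^2 %*% ssy) / sum(ssy))
  out <- setNames(rep(NA_real_, nrow(intensity)), rownames(intensity))
  out[!drop] <- vip
  out
}

#' Differential-metabolite screen (VIP and fold-change gates)
#'
#' A metabolite is differential iff its PLS-DA VIP is at least
#' `vip_threshold` and its fold change passes the two-sided gate
#' (`FC >= fc_hi` for up, `FC <= fc_lo` for down). Defaults follow the
#' standard UPLC-MS screening rule: VIP >= 1, FC >= 2 or <= 0.5.
#'
#' @inheritParams plsda_vip
#' @param vip_threshold minimum VIP.
#' @param fc_hi,fc_lo upper/lower fold-change gates.
#' @param n_components PLS components for the VIP model.
#' @return data.frame of class `screen_result`: `metabolite`,
#'   `fold_change`, `vip`, `differential`, `direction`
#'   (`"up"`/`"down"`/`"ns"`).
#' @export
differential_metabolites <- function(intensity, group, vip_threshold = 1,
                                     fc_hi = 2, fc_lo = 0.5,
                                     n_components = 2L) {
  fc <- met_fold_change(intensity, group)
  vip <- plsda_vip(intensity, group, n_components)
  fc_pass <- fc >= fc_hi | fc <= fc_lo
  diff <- !is.na(vip) & vip >= vip_threshold & fc_pass
  out <- data.frame(
    metabolite = names(fc) %||% as.character(seq_along(fc)),
    fold_change = unname(fc),
    vip = unname(vip),
    differential = unname(diff),
    direction = ifelse(diff & fc >= fc_hi, "up",
                       ifelse(diff & fc <= fc_lo, "down", "ns")),
    stringsAsFactors = FALSE
  )
  class(out) <- c("screen_result", "data.frame")
  out
}
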