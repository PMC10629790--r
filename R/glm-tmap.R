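#' Build a design matrix from a covariate table
#'
#' Group enters as a 0/1 indicator; `sex` and `site` are one-hot encoded
#' with one level dropped per factor; `age` and `tiv` enter as given.
#' The resulting t-maps are invariant to affine rescaling of any covariate
#' column and to which factor level is dropped.
#'
#' @param covariates data.frame with a `group` column (0/1 or two-level
#'   factor) and any of `age`, `sex`, `site`, `tiv`.
#' @param covars character vector of covariate names to include.
#' @param contrast name of the predictor tested (default `"group"`).
#' @param direction `+1` tests case > control, `-1` control > case; sets
#'   which group difference maps to positive t.
#' @return object of class `design_matrix`: list with `X`, `contrast`
#'   (numeric vector), `names`, `direction_note`.
#' @export
design_matrix <- function(covariates, covars = character(0),
                          contrast = "group", direction = 1) {
  grp <- covariates$group
  if (is.factor(grp) || is.character(grp))
    grp <- as.integer(factor(grp)) - 1L
  if (!all(grp %in% c(0, 1))) stop("group must be two-level")
  X <- cbind(intercept = 1, group = grp)
  for (nm in covars) {
    v <- covariates[[nm]]
    if (is.null(v)) stop("covariate not found: ", nm)
    if (is.character(v) || is.factor(v)) {
      f <- factor(v)
      if (nlevels(f) > 1) {
        mm <- stats::model.matrix(~f)[, -1, drop = FALSE]
        colnames(mm) <- paste0(nm, levels(f)[-1])
        X <- cbind(X, mm)
      }
    } else {
      X <- cbind(X, as.numeric(v))
      colnames(X)[ncol(X)] <- nm
    }
  }
  X <- as.matrix(X)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[setdiff(seq_len(ncol(X)), qrX$pivot[seq_len(qrX$rank)])]
    stop("design is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  cvec <- as.numeric(colnames(X) == contrast) * direction
  if (all(cvec == 0)) stop("contrast column not in design: ", contrast)
  structure(list(X = X, contrast = cvec, names = colnames(X),
                 direction_note = if (direction >= 0)
                   "positive t = case > control" else
                   "positive t = control > case"),
            class = "design_matrix")
}

#' Fit a mass-univariate t-map
#'
#' Ordinary least squares of voxel intensities on the design, voxel by
#' voxel within the shared mask; t = c'beta / sqrt(sigma2 c'(X'X)^-1 c)
#' with sigma2 = RSS / df and df = n - rank(X). Voxels with zero residual
#' variance get NA t and are flagged, never silently zeroed.
#'
#' @param images list of [volume_image()] sharing shape, affine and mask.
#' @param design a [design_matrix()].
#' @return object of class `tmap`: list with `image` ([volume_image()] of t
#'   values, NA where undefined), `df`, `direction_note`, `n_undefined`.
#' @export
fit_tmap <- function(images, design) {
  stopifnot(inherits(design, "design_matrix"))
  if (!length(images)) stop("no images")
  shp <- dim(images[[1]]$data)
  for (im in images) {
    if (!identical(dim(im$data), shp) ||
        max(abs(im$affine - images[[1]]$affine)) > 1e-9)
      stop("all images must share shape and affine")
  }
  X <- design$X
  n <- nrow(X)
  if (length(images) != n) stop("number of images must match design rows")
  r <- qr(X)$rank
  df <- n - r
  if (df < 1) stop("no residual degrees of freedom")
  mask <- images[[1]]$mask
  Y <- vapply(images, function(im) im$data[mask], numeric(sum(mask)))
  Y <- t(Y)  # subjects x voxels
  XtXinv <- chol2inv(chol(crossprod(X)))
  B <- XtXinv %*% crossprod(X, Y)
  res <- Y - X %*% B
  rss <- colSums(res^2)
  cvec <- design$contrast
  cv <- as.numeric(t(cvec) %*% XtXinv %*% cvec)
  sigma2 <- rss / df
  se <- sqrt(sigma2 * cv)
  tval <- as.numeric(crossprod(cvec, B)) / se
  tval[se == 0] <- NA_real_
  tarr <- array(NA_real_, shp)
  tarr[mask] <- tval
  structure(list(image = volume_image(tarr, images[[1]]$affine, mask),
                 df = df, direction_note = design$direction_note,
                 n_undefined = sum(se == 0)),
            class = "tmap")
}

#' @export
print.tmap <- function(x, ...) {
  cat("<tmap> df =", x$df, "|", x$direction_note, "|",
      sum(x$image$mask), "voxels\n")
  invisible(x)
}

#' Correlate two t-maps over their shared mask
#'
#' @param a,b `tmap` objects on the same grid.
#' @return list with `r` (Pearson), `p` (two-tailed, from the t transform
#'   of r), `n_voxels`.
#' @export
correlate_tmaps <- function(a, b) {
  stopifnot(inherits(a, "tmap"), inherits(b, "tmap"))
  m <- a$image$mask & b$image$mask &
    is.finite(a$image$data) & is.finite(b$image$data)
  va <- a$image$data[m]; vb <- b$image$data[m]
  n <- length(va)
  if (n < 3) stop("need at least 3 shared masked voxels")
  if (stats::sd(va) == 0 || stats::sd(vb) == 0)
    stop("correlation undefined for a constant map")
  r <- stats::cor(va, vb)
  tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), n - 2)
  list(r = r, p = p, n_voxels = n)
}
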