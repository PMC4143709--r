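#' Construct a longitudinal trait panel
#'
#' @param subject_id character vector of subject identifiers.
#' @param raw subjects x T matrix of trait values (e.g. mmHg).
#' @param age numeric vector (years; baseline age).
#' @param sex 0/1 vector.
#' @param medication 0/1 matrix subjects x T (per-exam use indicator), or a
#'   single vector recycled across exams.
#' @param trait_name e.g. \code{"SBP"} or \code{"DBP"}.
#' @return object of class \code{trait_panel}: list with \code{subject_id},
#'   \code{raw}, \code{adjusted} (\code{NULL} until
#'   \code{\link{adjust_covariates}} is run) and \code{covariates}.
#' @export
trait_panel <- function(subject_id, raw, age, sex, medication,
                        trait_name = "trait") {
  raw <- as.matrix(raw)
  n <- nrow(raw); T <- ncol(raw)
  if (is.null(colnames(raw))) colnames(raw) <- paste0("trait_t", seq_len(T) - 1L)
  if (!is.matrix(medication)) medication <- matrix(medication, n, T)
  stopifnot(length(subject_id) == n, length(age) == n, length(sex) == n,
            nrow(medication) == n, ncol(medication) == T,
            all(sex %in% 0:1), all(medication %in% 0:1))
  if (is.null(colnames(medication)))
    colnames(medication) <- paste0("med_t", seq_len(T) - 1L)
  structure(list(subject_id = as.character(subject_id), raw = raw,
                 adjusted = NULL,
                 covariates = list(age = age, sex = sex,
                                   medication = medication),
                 trait_name = trait_name),
            class = "trait_panel")
}

#' @export
print.trait_panel <- function(x, ...) {
  cat("trait_panel (", x$trait_name, "): ", nrow(x$raw), " subjects x ",
      ncol(x$raw), " time points; adjusted: ",
      if (is.null(x$adjusted)) "no" else "yes", "\n", sep = "")
  invisible(x)
}

#' Residualize traits on covariates, one time point at a time
#'
#' For each exam t independently, ordinary least squares of the trait on
#' intercept, age, sex, age x sex, and medication at that exam; the
#' residuals become the adjusted values used for trajectory clustering.
#' Collinear design columns are dropped (with a warning), as in \code{lm}.
#'
#' @param panel a \code{trait_panel}.
#' @return the panel with \code{adjusted} filled; per-exam fitted
#'   coefficients kept in attribute \code{"fits"}.
#' @export
adjust_covariates <- function(panel) {
  stopifnot(inherits(panel, "trait_panel"))
  n <- nrow(panel$raw); T <- ncol(panel$raw)
  if (n < 6) stop("too few subjects for covariate adjustment")
  adj <- panel$raw
  fits <- vector("list", T)
  cv <- panel$covariates
  for (t in seq_len(T)) {
    df <- data.frame(y = panel$raw[, t], age = cv$age, sex = cv$sex,
                     med = cv$medication[, t])
    ok <- stats::complete.cases(df[c("age", "sex", "med")])
    if (!all(ok)) stop("covariates must be complete")
    fit <- stats::lm(y ~ age + sex + age:sex + med, data = df,
                     na.action = stats::na.exclude)
    if (anyNA(stats::coef(fit)))
      warning("collinear covariate column(s) dropped at time point ", t - 1L)
    adj[, t] <- stats::residuals(fit)
    fits[[t]] <- stats::coef(fit)
  }
  panel$adjusted <- adj
  attr(panel, "fits") <- fits
  panel
}

#' Assemble per-subject trajectory vectors
#'
#' Returns the adjusted subjects x T matrix consumed by
#' \code{\link{cluster_phenotypes}}. A subject missing some (not all) time
#' points has gaps filled by carrying the last observed adjusted value
#' forward (leading gaps are back-filled from the first observed value);
#' affected subjects are flagged in attribute \code{"filled"}.
#'
#' @param panel a \code{trait_panel} with \code{adjusted} present.
#' @return numeric matrix, rows in input subject order.
#' @export
assemble_vectors <- function(panel) {
  stopifnot(inherits(panel, "trait_panel"))
  if (is.null(panel$adjusted))
    stop("run adjust_covariates() before assembling trajectories")
  M <- panel$adjusted
  rownames(M) <- panel$subject_id
  if (!anyNA(M)) return(M)
  all_missing <- rowSums(!is.na(M)) == 0
  if (any(all_missing))
    stop("subject(s) with no observed time points: ",
         paste(panel$subject_id[all_missing], collapse = ", "))
  filled <- which(rowSums(is.na(M)) > 0)
  for (i in filled) {
    v <- M[i, ]
    obs <- which(!is.na(v))
    for (t in seq_along(v)) {
      if (is.na(v[t])) {
        prev <- obs[obs < t]
        v[t] <- if (length(prev)) v[max(prev)] else v[min(obs)]
      }
    }
    M[i, ] <- v
  }
  attr(M, "filled") <- panel$subject_id[filled]
  M
}
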