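#' Save and load fitted models as JSON sidecars
#'
#' Posture models and blood-pressure calibrations are plain parameter sets;
#' persisting them as JSON keeps them inspectable and diffable next to the
#' session files they were fitted on.
#'
#' @param model a [fit_posture_model()] result.
#' @param path JSON file path.
#' @return `path`, invisibly (writers); the restored object (readers).
#' @export
save_posture_model <- function(model, path) {
  stopifnot(inherits(model, "posture_model"))
  obj <- list(
    n_clusters = model$n_clusters, weights = model$weights,
    means = model$means, covs = lapply(model$covs, as.vector),
    cluster_to_posture = model$cluster_to_posture,
    gravity_scale = model$gravity_scale, seed = model$seed,
    sample_budget = model$sample_budget,
    logdens_floor = model$logdens_floor,
    targets = lapply(model$targets, as.vector),
    loglik = model$loglik)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_posture_model
#' @param path JSON file written by [save_posture_model()].
#' @export
load_posture_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  d <- 3L
  covs <- obj$covs
  if (is.matrix(covs)) covs <- lapply(seq_len(nrow(covs)), function(i) covs[i, ])
  model <- list(
    n_clusters = obj$n_clusters, weights = as.numeric(obj$weights),
    means = matrix(as.numeric(obj$means), ncol = d,
                   dimnames = list(NULL, c("x", "y", "z"))),
    covs = lapply(covs, function(v) matrix(as.numeric(v), d, d)),
    cluster_to_posture = as.character(obj$cluster_to_posture),
    loglik = as.numeric(obj$loglik),
    gravity_scale = obj$gravity_scale, sample_budget = obj$sample_budget,
    seed = obj$seed, targets = lapply(obj$targets, as.numeric),
    logdens_floor = obj$logdens_floor)
  class(model) <- "posture_model"
  model
}

#' @rdname save_posture_model
#' @param calib a [fit_bp_calibration()] result.
#' @export
save_bp_calibration <- function(calib, path) {
  stopifnot(inherits(calib, "bp_calibration"))
  jsonlite::write_json(unclass(calib), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_posture_model
#' @export
load_bp_calibration <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (side in c("sbp", "dbp"))
    if (!is.null(obj[[side]]))
      obj[[side]] <- stats::setNames(as.numeric(obj[[side]]), c("a_pat", "b_hr", "c"))
  class(obj) <- "bp_calibration"
  obj
}
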