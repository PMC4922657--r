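# JSON archives for fitted models: the flat parameter vector in canonical
# packing order plus the configuration and diagnostics, written at full
# numeric precision so a pipeline rerun from the same config and seed
# produces byte-identical files.

#' Write / read a fitted HSM archive
#'
#' Stores the packed parameter vector, the configuration it was fitted
#' under, the restart table and optimizer diagnostics as JSON.
#'
#' @param fit an `hsm_fit`.
#' @param path file path (conventionally `.json`).
#' @return `write_hsm_fit`: `path` invisibly; `read_hsm_fit`: an `hsm_fit`.
#' @export
write_hsm_fit <- function(fit, path) {
  cfg <- fit$config
  obj <- list(
    type = "hsm_fit",
    config = list(s1 = cfg$s1, s2 = cfg$s2, s3 = cfg$s3, gamma = cfg$gamma,
                  p = cfg$p, n_restarts = cfg$n_restarts, seed = cfg$seed,
                  maxit = cfg$maxit, factr = cfg$factr),
    theta = pack_params(fit$params),
    final_loglik = fit$final_loglik, init_loglik = fit$init_loglik,
    train_performance = fit$train_performance,
    converged = fit$converged, seed = fit$seed,
    restarts = fit$restarts)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_hsm_fit
#' @export
read_hsm_fit <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$type, "hsm_fit")) stop("not an HSM fit archive: ", path)
  cfg <- hsm_config(s3 = obj$config$s3, s1 = obj$config$s1,
                    gamma = obj$config$gamma, p = obj$config$p,
                    n_restarts = obj$config$n_restarts, seed = obj$config$seed,
                    maxit = obj$config$maxit, factr = obj$config$factr)
  cfg$s2 <- obj$config$s2
  structure(list(params = unpack_params(obj$theta, cfg),
                 final_loglik = obj$final_loglik,
                 init_loglik = obj$init_loglik,
                 train_performance = obj$train_performance,
                 converged = obj$converged, seed = obj$seed,
                 restarts = as.data.frame(obj$restarts), config = cfg),
            class = "hsm_fit")
}

#' Write / read an rLN population archive
#'
#' @param models an `rln_population`.
#' @param path file path.
#' @return `write_rln_population`: `path` invisibly; `read_rln_population`:
#'   an `rln_population`.
#' @export
write_rln_population <- function(models, path) {
  obj <- list(type = "rln_population",
              p = models[[1]]$p,
              neurons = lapply(models, function(m)
                list(kernel = m$kernel, alpha_reg = m$alpha_reg,
                     centers = m$nonlinearity$centers,
                     values = m$nonlinearity$values)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_rln_population
#' @export
read_rln_population <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$type, "rln_population"))
    stop("not an rLN archive: ", path)
  p <- obj$p
  models <- lapply(obj$neurons, function(nr) {
    structure(list(kernel = unlist(nr$kernel), p = p,
                   alpha_reg = nr$alpha_reg,
                   nonlinearity = structure(
                     list(centers = unlist(nr$centers),
                          values = unlist(nr$values)),
                     class = "rln_nonlinearity")),
              class = "rln_model")
  })
  class(models) <- "rln_population"
  models
}
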