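#' Configuration of the full enhancement pipeline
#'
#' Bundles the parameters of the three stages plus metric flags. The
#' defaults are the working point of the method: `sigma_s = 60`,
#' `sigma_r = 0.4` for the background estimate, fusion factor `a = 5`,
#' PDE constants `k = 1` (byte scale), `dt = 0.1`, 10 steps, and a 3x3
#' relaxed median with `alpha = 3`, `omega = 7`.
#'
#' @param nc An [nc_params()] object.
#' @param fusion A [fusion_params()] object.
#' @param pde A [pde_params()] object.
#' @param rmf An [rmf_params()] object.
#' @param fov_threshold Threshold for [estimate_fov()] when no FOV mask is
#'   supplied.
#' @param invert_for_metrics,fov_only_fuzziness Flags forwarded to
#'   [enhancement_report()].
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(nc = nc_params(), fusion = fusion_params(),
                            pde = pde_params(), rmf = rmf_params(),
                            fov_threshold = 0.06,
                            invert_for_metrics = FALSE,
                            fov_only_fuzziness = FALSE) {
  stopifnot(inherits(nc, "nc_params"), inherits(fusion, "fusion_params"),
            inherits(pde, "pde_params"), inherits(rmf, "rmf_params"))
  check_scalar(fov_threshold, "fov_threshold", lower = 0, upper = 1,
               strict_lower = TRUE)
  structure(list(nc = nc, fusion = fusion, pde = pde, rmf = rmf,
                 fov_threshold = as.numeric(fov_threshold),
                 invert_for_metrics = isTRUE(invert_for_metrics),
                 fov_only_fuzziness = isTRUE(fov_only_fuzziness)),
            class = "pipeline_config")
}

#' Enhance a fundus image
#'
#' Runs the full chain: background estimation by domain-transform
#' normalized convolution (J), background-suppressing fusion
#' (P = I - a(J - I)), fourth-order PDE diffusion and relaxed median
#' filtering. Stage wall-clock timings are recorded.
#'
#' @param img `H x W x 3` color array on the unit scale.
#' @param cfg A [pipeline_config()] object.
#' @param keep_intermediates Keep the background and fusion stages in the
#'   result (they cost no extra computation, only memory)?
#' @return A list of class `fundus_enhancement` with elements `enhanced`,
#'   and — when `keep_intermediates` — `background` (J), `fused` (P),
#'   `denoised_pde`; plus `config` and `timings` (seconds per stage).
#' @export
enhance <- function(img, cfg = pipeline_config(), keep_intermediates = TRUE) {
  check_color_image(img)
  if (!inherits(cfg, "pipeline_config"))
    stop("`cfg` must be a pipeline_config", call. = FALSE)
  tm <- function(expr) {
    t0 <- proc.time()[["elapsed"]]
    v <- force(expr)
    list(v = v, t = proc.time()[["elapsed"]] - t0)
  }
  s1 <- tm(nc_smooth(img, cfg$nc))
  s2 <- tm(fuse(img, s1$v, cfg$fusion))
  s3 <- tm(pde_denoise(s2$v, cfg$pde))
  s4 <- tm(relaxed_median(s3$v, cfg$rmf))
  out <- list(enhanced = s4$v)
  if (keep_intermediates) {
    out$background <- s1$v
    out$fused <- s2$v
    out$denoised_pde <- s3$v
  }
  out$config <- cfg
  out$timings <- c(nc = s1$t, fusion = s2$t, pde = s3$t, rmf = s4$t)
  structure(out, class = "fundus_enhancement")
}

#' @export
print.fundus_enhancement <- function(x, ...) {
  d <- dim(x$enhanced)
  cat(sprintf("Enhanced fundus image %d x %d\n", d[1], d[2]))
  cat("  stage timings (s):",
      paste(sprintf("%s %.2f", names(x$timings), x$timings),
            collapse = ", "), "\n")
  invisible(x)
}

#' Read / write a pipeline configuration as YAML
#'
#' The YAML mirrors the structure of [pipeline_config()] (`nc`, `fusion`,
#' `pde`, `rmf`, `flags` sections); parsing a serialized configuration
#' reproduces it exactly.
#'
#' @param cfg A [pipeline_config()] object.
#' @param path YAML file path.
#' @return `read_pipeline_config()`: the configuration object.
#' @export
write_pipeline_config <- function(cfg, path) {
  x <- list(
    nc = unclass(cfg$nc), fusion = unclass(cfg$fusion),
    pde = unclass(cfg$pde), rmf = unclass(cfg$rmf),
    flags = list(fov_threshold = cfg$fov_threshold,
                 invert_for_metrics = cfg$invert_for_metrics,
                 fov_only_fuzziness = cfg$fov_only_fuzziness))
  writeLines(yaml::as.yaml(x), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  fl <- x$flags %||% list()
  pipeline_config(
    nc = do.call(nc_params, x$nc %||% list()),
    fusion = do.call(fusion_params, x$fusion %||% list()),
    pde = do.call(pde_params, x$pde %||% list()),
    rmf = do.call(rmf_params, x$rmf %||% list()),
    fov_threshold = fl$fov_threshold %||% 0.06,
    invert_for_metrics = fl$invert_for_metrics %||% FALSE,
    fov_only_fuzziness = fl$fov_only_fuzziness %||% FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
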