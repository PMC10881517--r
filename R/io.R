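# Flat key-value (JSON) parameter configs and delimited-text curve I/O.

#' Load a bundled or user kinetic parameter set
#'
#' Parameter sets are flat key-value JSON files. The package bundles the
#' published fits for the tip-link interface (wild type and R113G mutant) and
#' the four Cdh23 length variants under `extdata/params`.
#'
#' @param name Preset name (one of [list_params_presets()]) or a path to a
#'   JSON file with the fields of [sliding_rebinding_params()].
#' @return A `"sliding_rebinding_params"` object (the JSON `label`, if any,
#'   is kept as an attribute).
#' @examples
#' wt <- load_params("interface_wt")
#' @export
load_params <- function(name) {
  path <- if (file.exists(name)) name else
    system.file("extdata", "params", paste0(name, ".json"),
                package = "tipbond")
  if (!nzchar(path) || !file.exists(path))
    stop("unknown parameter preset or missing file: ", name)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- sliding_rebinding_params(
    k_minus1_0 = cfg$k_minus1_0, x_beta = cfg$x_beta,
    k_plus1 = cfg$k_plus1 %||% 0, k_plus2 = cfg$k_plus2 %||% 0,
    F_C1 = cfg$F_C1 %||% 58, F_C2 = cfg$F_C2 %||% 100,
    n = cfg$n %||% 1, kBT = cfg$kBT %||% .KBT_DEFAULT,
    variant = cfg$variant %||% "WT")
  attr(p, "label") <- cfg$label
  p
}

#' @rdname load_params
#' @export
list_params_presets <- function() {
  sub("\\.json$", "",
      dir(system.file("extdata", "params", package = "tipbond"),
          pattern = "\\.json$"))
}

#' Write a kinetic parameter set as flat JSON
#'
#' @param params A [sliding_rebinding_params()] object.
#' @param path Output file path.
#' @export
write_params <- function(params, path) {
  validate_sliding_rebinding_params(params)
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Load bundled Bell unfolding parameters per step-height class
#'
#' @param name Preset name (default the Cdh23 EC1-27 class table) or path to
#'   a JSON file with a `classes` array.
#' @return A list of [unfolding_class_params()] objects, one per step class,
#'   ordered by step height.
#' @export
load_unfolding_classes <- function(name = "unfolding_classes_ec1_27") {
  path <- if (file.exists(name)) name else
    system.file("extdata", "params", paste0(name, ".json"),
                package = "tipbond")
  if (!nzchar(path) || !file.exists(path))
    stop("unknown unfolding preset or missing file: ", name)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(seq_len(nrow(cfg$classes)), function(i)
    unfolding_class_params(k_u0 = cfg$classes$k_u0[i],
                           x_beta_u = cfg$classes$x_beta_u[i],
                           step_height = cfg$classes$step_height[i]))
}

#' Read / write lifetime-force curves as delimited text
#'
#' Tab-separated with header columns `force_pN`, `lifetime_s` and optionally
#' `error_s`.
#'
#' @param path File path.
#' @return For the reader, a `"lifetime_force_curve"` object.
#' @export
read_lifetime_curve <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t")
  if (!all(c("force_pN", "lifetime_s") %in% names(df)))
    stop("curve file needs columns force_pN, lifetime_s")
  as_lifetime_force_curve(df$force_pN, df$lifetime_s, df$error_s)
}

#' @rdname read_lifetime_curve
#' @param curve A `"lifetime_force_curve"` object.
#' @export
write_lifetime_curve <- function(curve, path) {
  write.table(as.data.frame(curve), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read / write force-clamp lifetime datasets
#'
#' Tab-separated with columns `force_pN`, `lifetime_s`, `censored` (0/1).
#'
#' @param path File path.
#' @param max_duration Clamp duration in seconds used for censoring.
#' @return For the reader, a list of [clamp_dataset()] objects, one per
#'   distinct clamp force.
#' @export
read_clamp_datasets <- function(path, max_duration = 10) {
  df <- read.table(path, header = TRUE, sep = "\t")
  if (!all(c("force_pN", "lifetime_s", "censored") %in% names(df)))
    stop("dataset file needs columns force_pN, lifetime_s, censored")
  lapply(split(df, df$force_pN), function(d)
    clamp_dataset(clamp_force = d$force_pN[1], lifetimes = d$lifetime_s,
                  censored = as.logical(d$censored),
                  max_duration = max_duration))
}

#' @rdname read_clamp_datasets
#' @param datasets A list of [clamp_dataset()] objects.
#' @export
write_clamp_datasets <- function(datasets, path) {
  if (inherits(datasets, "clamp_dataset")) datasets <- list(datasets)
  df <- do.call(rbind, lapply(datasets, function(d)
    data.frame(force_pN = d$clamp_force, lifetime_s = d$lifetimes,
               censored = as.integer(d$censored))))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
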