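# File I/O and assay-unit conversion. Units are fixed at the file
# boundary: concentrations in mM, velocities in U mg^-1, uptake in Da,
# time in seconds.

#' Spectrophotometric assay specification
#'
#' Wavelength, differential extinction coefficient and cuvette path length
#' of a direct continuous assay. Presets exist for the two phosphorolysis
#' substrates followed in this package: adenosine (`"Ado"`, 265 nm,
#' delta-epsilon -1690 M^-1 cm^-1) and 7-methylguanosine (`"m7Guo"`,
#' 260 nm, -4600 M^-1 cm^-1). Short path lengths (0.5, 0.2, 0.1 cm)
#' extend the usable substrate concentration range upward.
#'
#' @param substrate `"Ado"`, `"m7Guo"`, or any label for a custom assay.
#' @param lambda_obs observation wavelength (nm); filled from the preset
#'   when available.
#' @param delta_eps differential molar extinction coefficient
#'   (M^-1 cm^-1, signed, non-zero).
#' @param path_cm cuvette path length (cm, > 0).
#' @return A list of class `"assay_spec"`.
#' @export
assay_spec <- function(substrate = "Ado", lambda_obs = NULL,
                       delta_eps = NULL, path_cm = 1) {
  presets <- list(Ado = list(lambda_obs = 265, delta_eps = -1690),
                  m7Guo = list(lambda_obs = 260, delta_eps = -4600))
  if (substrate %in% names(presets)) {
    if (is.null(lambda_obs)) lambda_obs <- presets[[substrate]]$lambda_obs
    if (is.null(delta_eps)) delta_eps <- presets[[substrate]]$delta_eps
  }
  if (is.null(lambda_obs) || is.null(delta_eps))
    stop("custom substrates need explicit 'lambda_obs' and 'delta_eps'",
         call. = FALSE)
  if (delta_eps == 0) stop("'delta_eps' must be non-zero", call. = FALSE)
  if (path_cm <= 0) stop("'path_cm' must be positive", call. = FALSE)
  structure(list(substrate = substrate, lambda_obs = lambda_obs,
                 delta_eps = delta_eps, path_cm = path_cm),
            class = "assay_spec")
}

#' Convert an absorbance slope to a reaction rate
#'
#' Beer-Lambert conversion of a continuous-assay absorbance slope to a
#' molar rate: `rate = dA_dt / (delta_eps * path_cm)`. For
#' substrate-consumption assays with a negative differential extinction
#' coefficient, a negative absorbance slope yields a positive rate.
#'
#' @param dA_dt absorbance slope (AU per minute); vectorized.
#' @param spec an [assay_spec()].
#' @return Rate in M per minute.
#' @export
#' @examples
#' absorbance_slope_to_rate(-1.69e-3, assay_spec("Ado")) # 1e-6 M/min
absorbance_slope_to_rate <- function(dA_dt, spec) {
  stopifnot(inherits(spec, "assay_spec"))
  dA_dt / (spec$delta_eps * spec$path_cm)
}

#' Read / write initial-velocity CSV files
#'
#' The on-disk dialect is a UTF-8, comma-separated file with "." decimals
#' and header columns `c0_mM`, `v0_Umg`, and optionally `sd_Umg` and
#' `n_rep`. `read_velocity_csv` reports malformed rows (non-numeric cells,
#' negative concentrations) with their line numbers; a file with a header
#' but no data rows is an error. `write_velocity_csv` followed by
#' `read_velocity_csv` is the identity up to numeric representation.
#'
#' @param path file path.
#' @return `read_velocity_csv`: a [velocity_dataset()].
#' @export
read_velocity_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  required <- c("c0_mM", "v0_Umg")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (nrow(df) == 0L)
    stop("file '", path, "' has a header but no data rows", call. = FALSE)
  num <- function(col, name) {
    if (is.null(col)) return(NULL)
    x <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(x) & !(is.na(col) | col == "" | col == "NA"))
    if (length(bad))
      stop(sprintf("non-numeric value in column '%s' at line(s) %s",
                   name, paste(bad + 1L, collapse = ", ")), call. = FALSE)
    x
  }
  c0 <- num(df$c0_mM, "c0_mM")
  neg <- which(c0 < 0)
  if (length(neg))
    stop("negative concentration at line(s) ",
         paste(neg + 1L, collapse = ", "), call. = FALSE)
  velocity_dataset(
    c0 = c0,
    v0 = num(df$v0_Umg, "v0_Umg"),
    sd = if ("sd_Umg" %in% names(df)) num(df$sd_Umg, "sd_Umg")
         else NA_real_,
    n_rep = if ("n_rep" %in% names(df)) {
      nr <- num(df$n_rep, "n_rep"); nr[is.na(nr)] <- 1; as.integer(nr)
    } else 1L)
}

#' @rdname read_velocity_csv
#' @param dataset a [velocity_dataset()].
#' @export
write_velocity_csv <- function(dataset, path) {
  dataset <- as_velocity_dataset(dataset)
  out <- data.frame(c0_mM = dataset$c0, v0_Umg = dataset$v0,
                    sd_Umg = dataset$sd, n_rep = dataset$n_rep)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write per-peptide HDX uptake CSV files
#'
#' Long-format dialect with columns `peptide_id`, `start`, `end`, `state`,
#' `time_s`, `replicate`, `uptake_da`.
#'
#' @param path file path.
#' @return `read_uptake_csv`: a named list of [uptake_series()], one per
#'   (peptide, state).
#' @export
read_uptake_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("peptide_id", "start", "end", "state", "time_s",
                "replicate", "uptake_da")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  lapply(split(df, interaction(df$peptide_id, df$state, drop = TRUE)),
         function(s) uptake_series(s$peptide_id[1], s$start[1], s$end[1],
                                   s$state[1], s$time_s, s$replicate,
                                   s$uptake_da))
}

#' @rdname read_uptake_csv
#' @param series an [uptake_series()] or list of them.
#' @export
write_uptake_csv <- function(series, path) {
  if (inherits(series, "uptake_series")) series <- list(series)
  df <- do.call(rbind, lapply(series, as.data.frame))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
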