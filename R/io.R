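# Delimited-text I/O for configurations, source series and trajectories.

#' Load a simulation configuration from YAML
#'
#' Recognized top-level blocks (all optional; omitted blocks fall back to
#' the reference configuration): `geometry`, `ions` (list of records with
#' `name`, `valence`, `diffusion_constant`, `baseline_concentration`),
#' `constants` (`temperature`), `solver` (`dt`, `include_diffusion`,
#' `duration`, `record_stride`, `conc_stride`), `generator` (fields of
#' [population_params()]), `decay` (`subvolume`, `shifts` keyed by ion).
#'
#' @param path YAML file path.
#' @return list with `config` (ions/geometry/constants), `options`
#'   (`knp_options`), `generator` (`knp_population_params` or `NULL`), and
#'   `decay` (list or `NULL`).
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  geometry <- do.call(ecs_geometry, raw$geometry %||% list())
  ions <- if (is.null(raw$ions)) default_ion_set() else {
    tab <- do.call(rbind, lapply(raw$ions, as.data.frame))
    ion_set(tab$name, tab$valence, tab$diffusion_constant,
            tab$baseline_concentration)
  }
  constants <- do.call(physical_constants, raw$constants %||% list())
  options <- do.call(solver_options, raw$solver %||% list())
  generator <- if (is.null(raw$generator)) NULL
  else do.call(population_params, raw$generator)
  list(config = list(ions = ions, geometry = geometry,
                     constants = constants),
       options = options, generator = generator, decay = raw$decay)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a trajectory as delimited text
#'
#' One tab-separated file per quantity: `potential.tsv` (time + one column
#' per subvolume, V), `diffusive_current.tsv` / `field_current.tsv` (time +
#' one column per interface, A), and `conc_<ion>.tsv` (time + one column per
#' subvolume, mol/m^3).
#'
#' @param trajectory a `knp_trajectory`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_trajectory <- function(trajectory, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  N <- nrow(trajectory$potential)
  paths <- character(0)
  wide <- function(times, M, prefix) {
    df <- data.frame(time = times, t(M))
    names(df) <- c("time", paste0(prefix, seq_len(nrow(M))))
    df
  }
  emit <- function(df, file) {
    p <- file.path(dir, file)
    utils::write.table(df, p, sep = "\t", row.names = FALSE, quote = FALSE)
    p
  }
  paths <- c(paths,
             emit(wide(trajectory$times, trajectory$potential, "V"),
                  "potential.tsv"),
             emit(wide(trajectory$times, trajectory$diffusive_current, "Id"),
                  "diffusive_current.tsv"),
             emit(wide(trajectory$times, trajectory$field_current, "If"),
                  "field_current.tsv"))
  for (ion in dimnames(trajectory$concentrations)[[1]]) {
    M <- matrix(trajectory$concentrations[ion, , ], N,
                length(trajectory$conc_times))
    paths <- c(paths, emit(wide(trajectory$conc_times, M, "c"),
                           paste0("conc_", ion, ".tsv")))
  }
  invisible(paths)
}

#' Read a trajectory written by [write_trajectory()]
#'
#' @param dir directory containing the `.tsv` files.
#' @return a list with the same recorded fields as a `knp_trajectory`
#'   (times, potential, currents, conc_times, concentrations).
#' @export
read_trajectory <- function(dir) {
  slurp <- function(file) {
    df <- utils::read.table(file.path(dir, file), header = TRUE, sep = "\t")
    list(times = df$time, values = t(as.matrix(df[, -1, drop = FALSE])))
  }
  V <- slurp("potential.tsv")
  Id <- slurp("diffusive_current.tsv")
  If <- slurp("field_current.tsv")
  conc_files <- list.files(dir, pattern = "^conc_.*\\.tsv$")
  ions <- sub("^conc_(.*)\\.tsv$", "\\1", conc_files)
  conc <- NULL; conc_times <- NULL
  if (length(conc_files)) {
    first <- slurp(conc_files[1])
    conc_times <- first$times
    conc <- array(NA_real_, c(length(ions), nrow(first$values),
                              length(conc_times)),
                  dimnames = list(ions, NULL, NULL))
    for (i in seq_along(conc_files))
      conc[i, , ] <- slurp(conc_files[i])$values
  }
  structure(list(times = V$times, potential = V$values,
                 diffusive_current = Id$values, field_current = If$values,
                 conc_times = conc_times, concentrations = conc),
            class = "knp_trajectory")
}

#' Write a source series as delimited text
#'
#' Long format with columns `time` (s), `subvolume`, `species` (ion name or
#' `"cap"` for the capacitive current) and `value` (mol/s for ions, A for
#' `"cap"`). Zero entries are omitted; the full time grid is declared in a
#' `# sample_dt` comment header so sparse series round-trip exactly.
#'
#' @param series a `knp_sources` object.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_source_series <- function(series, path) {
  ion_names <- dimnames(series$ion_fluxes)[[1]]
  nt <- length(series$times)
  N <- dim(series$capacitive)[1]
  rows <- list()
  for (k in seq_along(ion_names)) {
    nz <- which(series$ion_fluxes[k, , ] != 0, arr.ind = TRUE)
    if (nrow(nz))
      rows[[length(rows) + 1]] <- data.frame(
        time = series$times[nz[, 2]], subvolume = nz[, 1],
        species = ion_names[k],
        value = series$ion_fluxes[k, , ][nz])
  }
  nz <- which(series$capacitive != 0, arr.ind = TRUE)
  if (nrow(nz))
    rows[[length(rows) + 1]] <- data.frame(
      time = series$times[nz[, 2]], subvolume = nz[, 1],
      species = "cap", value = series$capacitive[nz])
  df <- if (length(rows)) do.call(rbind, rows)
  else data.frame(time = numeric(0), subvolume = integer(0),
                  species = character(0), value = numeric(0))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sample_dt=%.17g n_samples=%d",
                     series$sample_dt, nt), con)
  utils::write.table(df[order(df$time, df$subvolume, df$species), ],
                     con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a source series written by [write_source_series()] or exported from
#' an external neuron simulator
#'
#' @param path input file (see [write_source_series()] for the format).
#' @param ions,geometry configuration the series must match.
#' @return a `knp_sources` object.
#' @export
read_source_series <- function(path, ions, geometry) {
  header <- readLines(path, n = 1)
  if (!grepl("^# sample_dt=", header))
    stop("missing '# sample_dt=... n_samples=...' header line")
  sample_dt <- as.numeric(sub("^# sample_dt=([^ ]+) .*$", "\\1", header))
  nt <- as.integer(sub("^.* n_samples=([0-9]+)$", "\\1", header))
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  N <- geometry$n_subvolumes
  K <- nrow(ions)
  times <- if (is.finite(sample_dt)) (seq_len(nt) - 1) * sample_dt else 0
  ion_fluxes <- array(0, c(K, N, nt))
  capacitive <- matrix(0, N, nt)
  if (nrow(df)) {
    ti <- if (is.finite(sample_dt)) as.integer(round(df$time / sample_dt)) + 1L
    else rep(1L, nrow(df))
    if (any(ti < 1 | ti > nt))
      stop("sample times fall outside the declared grid")
    if (any(df$subvolume < 1 | df$subvolume > N))
      stop("subvolume index out of range")
    is_cap <- df$species == "cap"
    capacitive[cbind(df$subvolume[is_cap], ti[is_cap])] <- df$value[is_cap]
    k <- match(df$species[!is_cap], ions$name)
    if (anyNA(k))
      stop("unknown species in source file: ",
           paste(unique(df$species[!is_cap][is.na(k)]), collapse = ", "))
    ion_fluxes[cbind(k, df$subvolume[!is_cap], ti[!is_cap])] <-
      df$value[!is_cap]
  }
  source_series(times, ion_fluxes, capacitive, ions, geometry)
}

#' Write a spectrum or depth profile as delimited text
#'
#' @param x a `knp_spectrum`, or a profile matrix from
#'   [time_average_profile()].
#' @param path output file.
#' @param units unit annotation written into the header.
#' @return invisibly, `path`.
#' @export
write_diagnostic <- function(x, path, units = "") {
  if (inherits(x, "knp_spectrum")) {
    df <- data.frame(frequency_Hz = x$frequencies, power = x$power)
    names(df)[2] <- paste0("power", if (nzchar(units)) paste0("_", units))
  } else {
    df <- data.frame(index = seq_len(nrow(x)), x)
    labels <- colnames(x) %||% paste0("interval", seq_len(ncol(x)))
    names(df) <- c("index",
                   paste0(labels, if (nzchar(units)) paste0("_", units)))
  }
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
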