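#' Write a trajectory to CSV
#'
#' Plain CSV with header `time_yr,T_K,A`, preceded by `#`-prefixed
#' metadata lines (`dt`, `stride`, `epsilon`, `seed`, `gamma`).  Values
#' are written with 17 significant digits so that a read/write round trip
#' is exact.
#'
#' @param traj A `climate_trajectory`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "climate_trajectory"))
  m <- traj$meta
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vegclim trajectory",
               sprintf("# dt=%.17g", m$dt),
               sprintf("# stride=%d", m$stride),
               sprintf("# epsilon=%.17g", m$epsilon),
               sprintf("# seed=%s", format(m$seed)),
               sprintf("# gamma=%.17g", m$params$gamma),
               "time_yr,T_K,A"), con)
  writeLines(sprintf("%.17g,%.17g,%.17g", traj$times, traj$T, traj$A), con)
  invisible(path)
}

#' Read a trajectory written by [write_trajectory()]
#'
#' Validates the header, that times are strictly increasing with a uniform
#' step, and the state invariants (`A` in `[0, 1]`, `T` finite positive).
#'
#' @param path CSV file.
#' @param params Optional [climate_params()] to attach as metadata.
#' @return A `climate_trajectory`.
#' @export
read_trajectory <- function(path, params = NULL) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  if (!length(body) || body[1L] != "time_yr,T_K,A")
    stop("malformed trajectory file: expected header 'time_yr,T_K,A'",
         call. = FALSE)
  get_meta <- function(key, default = NA_real_) {
    hit <- grep(sprintf("^# %s=", key), meta_lines, value = TRUE)
    if (!length(hit)) return(default)
    as.numeric(sub(sprintf("^# %s=", key), "", hit[1L]))
  }
  dat <- utils::read.csv(text = body)
  if (ncol(dat) != 3L || anyNA(dat))
    stop("malformed trajectory file: row/column mismatch", call. = FALSE)
  if (any(dat$A < 0 | dat$A > 1))
    stop("invalid trajectory: A outside [0, 1]", call. = FALSE)
  if (any(!is.finite(dat$T_K) | dat$T_K <= 0))
    stop("invalid trajectory: non-finite or non-positive T", call. = FALSE)
  dts <- diff(dat$time_yr)
  if (any(dts <= 0) || (length(dts) > 1 && diff(range(dts)) > 1e-9))
    stop("invalid trajectory: times must increase with a uniform step",
         call. = FALSE)
  if (is.null(params)) params <- climate_params(gamma = get_meta("gamma", 0.02))
  new_trajectory(as.matrix(dat), params,
                 dt = get_meta("dt", dts[1L]),
                 stride = as.integer(get_meta("stride", 1)),
                 epsilon = get_meta("epsilon", 0),
                 seed = as.integer(get_meta("seed")))
}

config_keys <- function() {
  c("C_T", "Q0", "p", "alpha_v", "alpha_g", "alpha_max", "alpha_min",
    "T_alpha_l", "T_alpha_u", "B0", "B1", "T_opt", "k", "gamma")
}

noise_keys <- function() c("epsilon", "seed", "dt", "t_max")

#' Load a parameter configuration
#'
#' Reads a flat key-value file (JSON, or YAML when the `yaml` package is
#' available) holding any subset of the model parameter keys
#' (`C_T`, `Q0`, `p`, `alpha_v`, `alpha_g`, `alpha_max`, `alpha_min`,
#' `T_alpha_l`, `T_alpha_u`, `B0`, `B1`, `T_opt`, `k`, `gamma`) and the
#' noise keys (`epsilon`, `seed`, `dt`, `t_max`).  Missing model keys take
#' the default calibration; entries in `overrides` (e.g. command-line
#' flags) take precedence over the file.  Unknown keys, non-numeric
#' values, and parameter-invariant violations raise named errors.
#'
#' @param path Config file, or `NULL` for pure defaults.
#' @param overrides Named list overriding file values.
#' @return A list with `params` (a [climate_params()]) and `noise` (named
#'   list of the resolved noise keys that were given).
#' @export
load_config <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path,
                                 call. = FALSE)
    vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("reading YAML configs requires the 'yaml' package",
             call. = FALSE)
      yaml::read_yaml(path)
    } else {
      jsonlite::read_json(path, simplifyVector = TRUE)
    }
  }
  vals[names(overrides)] <- overrides
  known <- c(config_keys(), noise_keys())
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (nm in names(vals))
    if (!is.numeric(vals[[nm]]) || length(vals[[nm]]) != 1L)
      stop(sprintf("config key '%s' must be a single number", nm),
           call. = FALSE)
  params <- do.call(climate_params, vals[intersect(names(vals),
                                                   config_keys())])
  list(params = params, noise = vals[intersect(names(vals), noise_keys())])
}

#' Serialize equilibria to JSON
#'
#' One record per equilibrium: `branch`, `T`, `A`, `eig_re`, `eig_im`,
#' `stability`.
#'
#' @param eqs A `climate_equilibria` object.
#' @param path Output file, or `NULL` to return the JSON string.
#' @export
write_equilibria_json <- function(eqs, path = NULL) {
  recs <- lapply(eqs, function(e) {
    list(branch = e$branch, T = e$state[["T"]], A = e$state[["A"]],
         eig_re = Re(e$eigenvalues), eig_im = Im(e$eigenvalues),
         stability = e$stability)
  })
  if (is.null(path))
    return(jsonlite::toJSON(recs, auto_unbox = TRUE, digits = NA))
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Serialize a sweep result to JSON
#'
#' @param sweep An `epsilon_sweep` object.
#' @param path Output file, or `NULL` to return the JSON string.
#' @export
write_sweep_json <- function(sweep, path = NULL) {
  x <- list(gamma = sweep$gamma, eps_grid = sweep$eps_grid,
            prob = sweep$prob, ci_lo = sweep$ci_lo, ci_hi = sweep$ci_hi,
            n_runs = sweep$n_runs, ci_method = sweep$ci_method,
            window = list(lo = sweep$window[["lo"]],
                          hi = sweep$window[["hi"]]),
            criterion = sweep$criterion)
  if (is.null(path)) return(jsonlite::toJSON(x, auto_unbox = TRUE,
                                             digits = NA))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a density estimate as CSV (`bin_lo_K, bin_hi_K, mass`)
#'
#' @param dens A `density_estimate`.
#' @param path Output file.
#' @export
write_density_csv <- function(dens, path) {
  n <- length(dens$mass)
  df <- data.frame(bin_lo_K = dens$bin_edges[seq_len(n)],
                   bin_hi_K = dens$bin_edges[seq_len(n) + 1L],
                   mass = dens$mass)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
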