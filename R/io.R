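#' Parse a scheme configuration file
#'
#' Human-editable structured text declaring a kinetic scheme.  Line types:
#' \preformatted{
#' scheme: cs_if
#' unit: uM                     # concentration unit of rate values (M or uM)
#' species: I A L AL ALs
#' reaction: I <-> A : k_ia, k_ai
#' reaction: A + L <-> AL : k_on, k_off
#' rate: k_ia = 3.8e-4
#' observable: fluor : I=1 A=1 AL=0.6 ALs=0.45 : baseline=0
#' }
#' Bimolecular rate constants declared under `unit: uM` are converted to
#' M^-1 s^-1 at parse time (the internal unit system is molar/seconds).
#' `serialize_scheme_config(parse_scheme_config(path))` is lossless up to
#' normalisation (one irreversible step per line, molar units).
#'
#' @param path file path.
#' @return a [kinetic_scheme()].
#' @export
parse_scheme_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  get_vals <- function(key) {
    sel <- grepl(paste0("^", key, ":"), lines)
    sub(paste0("^", key, ":\\s*"), "", lines[sel])
  }
  name <- get_vals("scheme"); name <- if (length(name)) name[1] else "scheme"
  unit <- get_vals("unit"); unit <- if (length(unit)) unit[1] else "M"
  if (!unit %in% c("M", "uM")) stop("unit must be 'M' or 'uM'")
  species <- strsplit(get_vals("species")[1], "[ ,]+")[[1]]
  reactions <- as.list(get_vals("reaction"))
  rate_lines <- get_vals("rate")
  rates <- numeric(0)
  for (rl in rate_lines) {
    kv <- strsplit(rl, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop("malformed rate line: ", rl)
    rates[trimws(kv[1])] <- as.numeric(trimws(kv[2]))
  }
  sc <- kinetic_scheme(species, reactions, rates, name = name)
  # unit conversion: bimolecular rates declared per uM become per M
  if (unit == "uM") {
    bim <- unique(vapply(Filter(function(st) length(st$reactants) == 2L,
                                sc$reactions), `[[`, character(1), "rate"))
    sc$rate_constants[bim] <- sc$rate_constants[bim] * 1e6
  }
  for (ol in get_vals("observable")) {
    parts <- trimws(strsplit(ol, ":", fixed = TRUE)[[1]])
    if (length(parts) < 2L) stop("malformed observable line: ", ol)
    coeff <- numeric(0)
    for (tok in strsplit(parts[2], "\\s+")[[1]]) {
      kv <- strsplit(tok, "=", fixed = TRUE)[[1]]
      coeff[kv[1]] <- as.numeric(kv[2])
    }
    baseline <- 0
    if (length(parts) >= 3L)
      baseline <- as.numeric(sub("^baseline\\s*=\\s*", "", parts[3]))
    sc$observables[[parts[1]]] <- list(coeff = coeff, baseline = baseline)
  }
  # re-validate with observables attached
  kinetic_scheme(sc$species, lapply(sc$reactions, identity),
                 sc$rate_constants, sc$observables, name = sc$name)
}

#' Serialize a kinetic scheme to the configuration format
#' @param scheme a [kinetic_scheme()].
#' @param path optional output file; when NULL the lines are returned.
#' @export
serialize_scheme_config <- function(scheme, path = NULL) {
  lines <- c(paste0("scheme: ", scheme$name),
             "unit: M",
             paste0("species: ", paste(scheme$species, collapse = " ")))
  for (st in scheme$reactions)
    lines <- c(lines, paste0("reaction: ", format_step(st)))
  for (nm in names(scheme$rate_constants))
    lines <- c(lines, sprintf("rate: %s = %s", nm,
                              fmt_num(scheme$rate_constants[[nm]])))
  for (nm in names(scheme$observables)) {
    ob <- scheme$observables[[nm]]
    lines <- c(lines, sprintf("observable: %s : %s : baseline=%s", nm,
                              paste(names(ob$coeff), fmt_num(ob$coeff),
                                    sep = "=", collapse = " "),
                              fmt_num(ob$baseline)))
  }
  if (!is.null(path)) { writeLines(lines, path); return(invisible(path)) }
  lines
}

#' Write a synthetic dataset to disk
#'
#' One CSV per trace plus a JSON manifest (kind, trace paths and metadata,
#' noise, provenance) and a sidecar `truth.json`.  The truth never enters
#' the data files or the manifest, so recovery tests stay honest.
#'
#' @param dataset a `kk_dataset`.
#' @param dir output directory (created if needed).
#' @param kind dataset kind recorded in the manifest.
#' @export
write_dataset <- function(dataset, dir,
                          kind = c("stopped-flow", "progress", "nmr-spectrum",
                                   "relaxation", "volumes", "summary")) {
  kind <- match.arg(kind)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- list()
  for (i in seq_along(dataset$traces)) {
    tr <- dataset$traces[[i]]
    fn <- sprintf("trace_%03d.csv", i)
    write_timeseries_csv(tr, file.path(dir, fn))
    meta <- tr$meta[setdiff(names(tr$meta), "kind")]
    entries[[i]] <- c(list(path = fn), meta,
                      if (!is.null(tr$sigma)) list(sigma = tr$sigma[1]))
  }
  manifest <- list(kind = kind, traces = entries,
                   noise = list(kind = "additive-gaussian",
                                sigma = dataset$provenance$noise_sigma %||% 0),
                   provenance = dataset$provenance[c("generator", "version", "seed")],
                   truth_path = "truth.json")
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(unclass_deep(dataset$truth), file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file.path(dir, "manifest.json"))
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

#' Load a dataset written by [write_dataset()]
#' @param dir directory containing `manifest.json`.
#' @param with_truth also load the truth sidecar (for recovery tests).
#' @return a `kk_dataset` (truth is NULL unless requested).
#' @export
load_dataset <- function(dir, with_truth = FALSE) {
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"))
  traces <- lapply(mf$traces, function(e) {
    p <- file.path(dir, e$path)
    if (!file.exists(p)) stop("manifest references missing file: ", e$path)
    ts <- load_timeseries_csv(p)
    ts$meta <- e[setdiff(names(e), c("path", "sigma"))]
    ts$meta <- lapply(ts$meta, function(v) if (is.list(v)) unlist(v) else v)
    if (!is.null(e$sigma)) ts$sigma <- as.numeric(e$sigma)
    ts
  })
  truth <- if (with_truth) jsonlite::read_json(file.path(dir, mf$truth_path),
                                               simplifyVector = TRUE) else NULL
  structure(list(traces = traces, truth = truth,
                 provenance = mf$provenance, kind = mf$kind),
            class = "kk_dataset")
}

#' Write a deterministic fit report
#'
#' Emits `<prefix>_params.csv` (machine readable: parameter, estimate, se,
#' CI bounds) and `<prefix>_report.txt` (human readable, including
#' convergence, flags, multistart provenance, seeds and package version).
#' Identical inputs give byte-identical files: no timestamps.
#'
#' @param result a `kk_fit` (or a list of named numbers for simple tables);
#'   an empty list yields a valid empty report.
#' @param prefix output path prefix.
#' @return invisible character vector of the files written.
#' @export
write_report <- function(result, prefix) {
  csv <- paste0(prefix, "_params.csv")
  txt <- paste0(prefix, "_report.txt")
  ver <- as.character(utils::packageVersion("confmodel"))
  if (inherits(result, "kk_fit")) {
    if (is.null(names(result$par)))
      names(result$par) <- paste0("p", seq_along(result$par))
    tab <- data.frame(parameter = names(result$par),
                      estimate = fmt_num(result$par),
                      se = fmt_num(result$se),
                      ci_lower = fmt_num(result$ci_lower),
                      ci_upper = fmt_num(result$ci_upper))
    utils::write.csv(tab, csv, row.names = FALSE, quote = FALSE)
    lines <- c("confmodel fit report",
               paste0("package_version: ", ver),
               paste0("converged: ", result$converged),
               paste0("iterations: ", result$iterations),
               paste0("rss: ", fmt_num(result$rss)),
               paste0("n_obs: ", result$n_obs),
               if (!is.null(result$multistart))
                 paste0("multistart: n_starts=", result$multistart$n_starts,
                        " seed=", result$multistart$seed),
               paste0("flags: ", if (length(result$flags))
                 paste(result$flags, collapse = "; ") else "none"),
               "parameters:",
               sprintf("  %s = %s (se %s)", names(result$par),
                       fmt_num(result$par), fmt_num(result$se)))
  } else {
    vals <- unlist(result)
    tab <- data.frame(parameter = names(vals) %||% character(0),
                      estimate = if (length(vals)) fmt_num(vals) else character(0))
    utils::write.csv(tab, csv, row.names = FALSE, quote = FALSE)
    lines <- c("confmodel report", paste0("package_version: ", ver),
               if (length(vals)) sprintf("  %s = %s", names(vals), fmt_num(vals))
               else "  (empty result set)")
  }
  writeLines(lines, txt)
  invisible(c(csv, txt))
}
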