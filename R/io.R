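CONFIG_TABLES <- c("rd", "kmc", "polymer", "output")

parse_config_value <- function(raw, path, lineno) {
  v <- trimws(raw)
  if (grepl("^\\[.*\\]$", v)) {
    inner <- trimws(substr(v, 2, nchar(v) - 1))
    if (!nzchar(inner)) return(list())
    return(lapply(strsplit(inner, ",")[[1]], parse_config_value,
                  path = path, lineno = lineno))
  }
  if (grepl('^".*"$', v) || grepl("^'.*'$", v))
    return(substr(v, 2, nchar(v) - 1))
  if (v %in% c("true", "false")) return(v == "true")
  num <- suppressWarnings(as.numeric(v))
  if (!is.na(num)) return(num)
  abort(sprintf("config '%s' line %d: cannot parse value `%s`",
                path, lineno, raw), class = "chromspread_parse_error")
}

#' Read a run configuration file
#'
#' Parses a flat TOML-dialect configuration with up to four tables --
#' `[rd]`, `[kmc]`, `[polymer]`, `[output]` -- whose keys mirror the
#' argument names of [rd_params()], [kmc_params()], the polymer generators
#' and the output writers.  Values are numbers, booleans (`true`/`false`),
#' quoted strings or flat arrays; `#` starts a comment.  Unknown tables or
#' keys are an error naming the offender, so typos cannot silently fall back
#' to defaults.
#'
#' @param path Path to the configuration file.
#' @return A named list of tables, each a named list of values.
#' @export
read_config <- function(path) {
  if (!file.exists(path))
    abort(sprintf("config file '%s' not found", path),
          class = "chromspread_parse_error")
  lines <- readLines(path)
  out <- list()
  table <- NULL
  known_keys <- list(
    rd = names(formals(rd_params)),
    kmc = names(formals(kmc_params)),
    polymer = c("walk_type", "n_beads", "n_configs", "contact_cutoff",
                "file"),
    output = c("dir", "bedgraph", "chrom", "bin_bp", "shell_dr"))
  for (i in seq_along(lines)) {
    ln <- trimws(sub("#.*$", "", lines[i]))
    if (!nzchar(ln)) next
    if (grepl("^\\[[A-Za-z_]+\\]$", ln)) {
      table <- gsub("\\[|\\]", "", ln)
      if (!table %in% CONFIG_TABLES)
        abort(sprintf("config '%s' line %d: unknown table [%s]",
                      path, i, table), class = "chromspread_parse_error")
      if (is.null(out[[table]])) out[[table]] <- list()
      next
    }
    if (!grepl("=", ln))
      abort(sprintf("config '%s' line %d: expected `key = value`", path, i),
            class = "chromspread_parse_error")
    if (is.null(table))
      abort(sprintf("config '%s' line %d: key outside any table", path, i),
            class = "chromspread_parse_error")
    key <- trimws(sub("=.*$", "", ln))
    if (!key %in% known_keys[[table]])
      abort(sprintf("config '%s' line %d: unknown key `%s` in [%s]",
                    path, i, key, table), class = "chromspread_parse_error")
    out[[table]][[key]] <-
      parse_config_value(sub("^[^=]*=", "", ln), path, i)
  }
  out
}

#' Build run parameters from a configuration
#'
#' @param config A list as returned by [read_config()].
#' @param overrides Named list applied on top of the `[rd]` table (CLI flags
#'   override the file).
#' @return An [rd_params()] object.
#' @export
config_to_rd_params <- function(config, overrides = list()) {
  args <- modifyList(config$rd %||% list(), overrides)
  do.call(rd_params, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

run_metadata <- function(run) {
  list(schema_version = 1L,
       package_version = run$version %||%
         as.character(packageVersion("chromspread")),
       model = if (inherits(run, "kmc_run")) "kmc" else "rd",
       mode = run$mode %||% NA_character_,
       seed = run$seed,
       n_samples = run$n_samples %||% NA_integer_,
       params = unclass(run$params))
}

fmt_tsv <- function(df) {
  cols <- vapply(df, function(col) {
    if (is.double(col)) sprintf("%.10g", col) else as.character(col)
  }, character(nrow(df)))
  if (nrow(df) == 1) cols <- matrix(cols, nrow = 1)
  c(paste(names(df), collapse = "\t"),
    apply(cols, 1, paste, collapse = "\t"))
}

#' Write a run to a directory of plain-text files
#'
#' Serializes a reaction-diffusion or Gillespie run as diff-able text: the
#' methylation profile, the per-sample lattice snapshots (rows of 0/1 with a
#' site-index header), particle counts, shell densities, the final particle
#' snapshot, and a `metadata.json` sidecar carrying the schema version, the
#' seed and a full parameter echo -- enough to reproduce the directory
#' exactly.
#'
#' @param run An `rd_run` or `kmc_run`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_samples <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- run_metadata(run)
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(fmt_tsv(run$profile), file.path(dir, "profile.tsv"))
  if (inherits(run, "rd_run")) {
    if (!is.null(run$samples)) {
      hdr <- paste(colnames(run$samples), collapse = "\t")
      rows <- apply(run$samples, 1, paste, collapse = "\t")
      writeLines(c(hdr, rows), file.path(dir, "lattice_samples.tsv"))
    }
    writeLines(fmt_tsv(run$counts), file.path(dir, "particle_counts.tsv"))
    writeLines(fmt_tsv(run$shells), file.path(dir, "shells.tsv"))
    writeLines(fmt_tsv(run$cprox), file.path(dir, "cprox.tsv"))
    writeLines(fmt_tsv(run$particles), file.path(dir, "particles_final.tsv"))
  }
  invisible(dir)
}

read_tsv_strict <- function(path) {
  if (!file.exists(path))
    abort(sprintf("expected file '%s' is missing", path),
          class = "chromspread_parse_error")
  lines <- readLines(path)
  if (length(lines) < 1)
    abort(sprintf("'%s' is empty", path), class = "chromspread_parse_error")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- length(fields[[1]])
  nf <- vapply(fields, length, integer(1))
  if (any(nf != ncol))
    abort(sprintf("parse error in '%s' at line %d: %d fields (header has %d)",
                  path, which(nf != ncol)[1], nf[nf != ncol][1], ncol),
          class = "chromspread_parse_error")
  if (length(lines) == 1)
    return(tibble::as_tibble(setNames(
      rep(list(numeric(0)), ncol), fields[[1]])))
  body <- do.call(rbind, fields[-1])
  df <- as.data.frame(body, stringsAsFactors = FALSE)
  names(df) <- fields[[1]]
  for (j in seq_along(df)) {
    num <- suppressWarnings(as.numeric(df[[j]]))
    if (!any(is.na(num))) df[[j]] <- num
  }
  tibble::as_tibble(df)
}

#' Read back a run directory
#'
#' Re-loads the files written by [write_samples()], verifying the metadata
#' sidecar first; a missing sidecar or a malformed table is an explicit
#' error (with the offending line for truncated files).
#'
#' @param dir Directory written by [write_samples()].
#' @return A list with `metadata` and the stored tables (`profile`, and for
#'   RD runs `samples`, `counts`, `shells`, `cprox`, `particles`).
#' @export
read_samples <- function(dir) {
  meta_path <- file.path(dir, "metadata.json")
  if (!file.exists(meta_path))
    abort(sprintf(
      "'%s' has no metadata.json sidecar; re-run write_samples() (analysis needs the parameter echo to interpret the tables)",
      dir), class = "chromspread_parse_error")
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  out <- list(metadata = meta,
              profile = read_tsv_strict(file.path(dir, "profile.tsv")))
  if (identical(meta$model, "rd")) {
    sf <- file.path(dir, "lattice_samples.tsv")
    if (file.exists(sf)) {
      tab <- read_tsv_strict(sf)
      out$samples <- as.matrix(tab)
    }
    out$counts <- read_tsv_strict(file.path(dir, "particle_counts.tsv"))
    out$shells <- read_tsv_strict(file.path(dir, "shells.tsv"))
    out$cprox <- read_tsv_strict(file.path(dir, "cprox.tsv"))
    out$particles <- read_tsv_strict(file.path(dir, "particles_final.tsv"))
  }
  out
}

#' Import a per-bin signal track
#'
#' Convenience hook for loading an external per-bin signal (for example a
#' binned ChIP-seq enrichment) for side-by-side plotting with simulated
#' profiles.  Accepts a two-column TSV (`bin`, `signal`, with header) or a
#' four-column bedGraph.  No fitting or comparison is performed.
#'
#' @param path File path.
#' @return A tibble with columns `bin` and `signal`.
#' @export
read_signal_track <- function(path) {
  first <- readLines(path, n = 1)
  if (grepl("\t", first) &&
      length(strsplit(first, "\t")[[1]]) == 4 &&
      !grepl("[A-Za-z]", strsplit(first, "\t")[[1]][2])) {
    df <- utils::read.delim(path, header = FALSE,
                            col.names = c("chrom", "start", "end", "signal"))
    return(tibble::tibble(bin = seq_len(nrow(df)), signal = df$signal))
  }
  df <- read_tsv_strict(path)
  if (!all(c("bin", "signal") %in% names(df)))
    abort(sprintf("'%s': expected columns `bin` and `signal`", path),
          class = "chromspread_parse_error")
  tibble::tibble(bin = df$bin, signal = df$signal)
}
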