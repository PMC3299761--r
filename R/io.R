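# Plain-text I/O: observation/truth/cohort/trace TSVs, a minimal
# transcript-space VCF dialect, key=value configuration files, and run
# manifests. Every writer's output is re-readable by the matching reader.

.obs_columns <- c("sample_id", "tissue", "gene", "site", "pos", "offset",
                  "region", "ref", "alt", "ref_count", "alt_count", "dbsnp",
                  "event_length", "synonymous", "ref_aa", "alt_aa", "descriptor")

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

read_tsv <- function(path, required = character(0), what = "table") {
  if (!file.exists(path)) {
    stop_med12("io_error", "cannot read ", what, ": no such file '", path, "'")
  }
  d <- tryCatch(
    utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "NA"),
    error = function(e) {
      stop_med12("io_error", "malformed ", what, " in '", path, "': ",
                 conditionMessage(e))
    })
  missing <- setdiff(required, names(d))
  if (length(missing)) {
    stop_med12("io_error", "'", path, "' lacks required column(s): ",
               paste(missing, collapse = ", "))
  }
  extra <- setdiff(names(d), required)
  if (length(required) && length(extra)) {
    warning("ignoring unknown column(s) in '", path, "': ",
            paste(extra, collapse = ", "), call. = FALSE)
  }
  d
}

#' Read and write observation tables
#'
#' Tab-separated, one row per sample x tissue x site, with the columns
#' documented in [simulate_pair()]. Unknown columns warn and are ignored;
#' missing required columns are an input error.
#'
#' @param obs Observation `data.frame`.
#' @param path File path.
#' @return `write_observations()` the path, invisibly;
#'   `read_observations()` the `data.frame`.
#' @export
write_observations <- function(obs, path) write_tsv(obs[, .obs_columns], path)

#' @rdname write_observations
#' @export
read_observations <- function(path) {
  d <- read_tsv(path, .obs_columns, "observation table")
  bad <- which(d$ref_count < 0 | d$alt_count < 0)
  if (length(bad)) {
    stop_med12("io_error", "negative read count at line ", bad[1L] + 1L,
               " of '", path, "'")
  }
  d[, .obs_columns]
}

#' Read and write cohort tables
#'
#' Columns: `sample`, `karyotype`, `race`, `multiplicity`, `size_cm`,
#' `age`, `med12_status`. The number of paired normal samples travels in a
#' `# n_normals=<k>` comment line.
#'
#' @param cohort Cohort `data.frame` (see [simulate_cohort()]).
#' @param path File path.
#' @return `write_cohort()` the path, invisibly; `read_cohort()` the
#'   `data.frame` with attribute `n_normals`.
#' @export
write_cohort <- function(cohort, path) {
  con <- file(path, "w")
  on.exit(close(con))
  n_normals <- attr(cohort, "n_normals")
  if (!is.null(n_normals)) writeLines(paste0("# n_normals=", n_normals), con)
  utils::write.table(cohort, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) {
    stop_med12("io_error", "cannot read cohort: no such file '", path, "'")
  }
  first <- readLines(path, n = 1L)
  n_normals <- NULL
  if (startsWith(first, "# n_normals=")) {
    n_normals <- as.integer(sub("# n_normals=", "", first, fixed = TRUE))
  }
  d <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                         na.strings = "NA")
  req <- c("sample", "med12_status")
  missing <- setdiff(req, names(d))
  if (length(missing)) {
    stop_med12("io_error", "'", path, "' lacks required column(s): ",
               paste(missing, collapse = ", "))
  }
  if (!is.null(n_normals)) attr(d, "n_normals") <- n_normals
  d
}

#' Write and read variants in the minimal transcript-space VCF dialect
#'
#' A deliberately small, fixed dialect for cDNA-space variants:
#' `##fileformat=VCFv4.2` header; CHROM is the gene/transcript label; POS
#' the cDNA base (intron-anchored positions carry their offset in INFO);
#' ID is `dbSNP` for known polymorphisms, else `.`; REF/ALT are literal
#' alleles (`.` when absent); QUAL and FILTER are `.`; INFO holds
#' `EVLEN=` (event length), `OFFSET=` (intronic offset), `SAMPLE=`,
#' `SITE=`, and optionally `CLASS=` and `DESC=`. No genotype columns.
#'
#' @param vars Variant `data.frame` (observation-schema rows, optionally
#'   with a `category` column).
#' @param path File path.
#' @return `write_minimal_vcf()` the path invisibly; `read_minimal_vcf()` a
#'   `data.frame` with the observation-schema columns it can recover.
#' @export
write_minimal_vcf <- function(vars, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=med12scan",
               paste0("##INFO=<ID=EVLEN,Number=1,Type=Integer,",
                      "Description=\"Event length in bases\">"),
               paste0("##INFO=<ID=OFFSET,Number=1,Type=Integer,",
                      "Description=\"Intronic offset (0 = exonic)\">"),
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(vars)) {
    category <- if (is.null(vars$category)) rep(NA_character_, nrow(vars))
                else vars$category
    descriptor <- if (is.null(vars$descriptor)) rep(NA_character_, nrow(vars))
                  else vars$descriptor
    info <- paste0("EVLEN=", vars$event_length,
                   ";OFFSET=", ifelse(is.na(vars$offset), 0L, vars$offset),
                   ";SAMPLE=", vars$sample_id,
                   ";SITE=", vars$site,
                   ifelse(is.na(category), "", paste0(";CLASS=", category)),
                   ifelse(is.na(descriptor), "", paste0(";DESC=", descriptor)))
    lines <- paste(vars$gene,
                   ifelse(is.na(vars$pos), 0L, vars$pos),
                   ifelse(vars$dbsnp, "dbSNP", "."),
                   vars$ref, vars$alt, ".", ".", info, sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname write_minimal_vcf
#' @export
read_minimal_vcf <- function(path) {
  if (!file.exists(path)) {
    stop_med12("io_error", "cannot read VCF: no such file '", path, "'")
  }
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1L], "##fileformat=VCF")) {
    stop_med12("io_error", "'", path, "' is not a VCF file")
  }
  body <- lines[!startsWith(lines, "#")]
  get_info <- function(info, key) {
    m <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([^;]*)"), info))
    vapply(m, function(g) if (length(g) == 2L) g[2L] else NA_character_,
           character(1))
  }
  if (!length(body)) {
    return(data.frame(sample_id = character(0), gene = character(0),
                      site = character(0), pos = integer(0),
                      offset = integer(0), ref = character(0),
                      alt = character(0), dbsnp = logical(0),
                      event_length = integer(0), category = character(0),
                      descriptor = character(0)))
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(f) != 8L)) {
    stop_med12("io_error", "malformed VCF record at data line ",
               which(lengths(f) != 8L)[1L], " of '", path, "'")
  }
  f <- do.call(rbind, f)
  info <- f[, 8L]
  data.frame(sample_id = get_info(info, "SAMPLE"),
             gene = f[, 1L],
             site = get_info(info, "SITE"),
             pos = as.integer(f[, 2L]),
             offset = as.integer(get_info(info, "OFFSET")),
             ref = f[, 4L], alt = f[, 5L],
             dbsnp = f[, 3L] == "dbSNP",
             event_length = as.integer(get_info(info, "EVLEN")),
             category = get_info(info, "CLASS"),
             descriptor = get_info(info, "DESC"))
}

#' Write and read a filter trace table
#'
#' @param trace Trace `data.frame` from [run_cascade()].
#' @param path File path.
#' @return The path, invisibly / the `data.frame`.
#' @export
write_trace <- function(trace, path) write_tsv(trace, path)

#' @rdname write_trace
#' @export
read_trace <- function(path) read_tsv(path, what = "trace")

#' Read and write flat key=value configuration files
#'
#' One `key=value` per line; `#` comments and blank lines are ignored.
#' Values that parse as numbers are returned numeric, `true`/`false` as
#' logical.
#'
#' @param path File path.
#' @param config Named list.
#' @return `read_config()` a named list; `write_config()` the path.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    stop_med12("io_error", "cannot read config: no such file '", path, "'")
  }
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (i in seq_along(lines)) {
    if (!grepl("=", lines[i], fixed = TRUE)) {
      stop_med12("io_error", "malformed config line ", i, ": '", lines[i], "'")
    }
    kv <- strsplit(lines[i], "=", fixed = TRUE)[[1L]]
    key <- trimws(kv[1L])
    val <- trimws(paste(kv[-1L], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num
                  else if (tolower(val) %in% c("true", "false")) tolower(val) == "true"
                  else val
  }
  out
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  writeLines(paste0(names(config), "=", vapply(config, as.character, character(1))),
             path)
  invisible(path)
}

#' Write a run manifest
#'
#' Records the subcommand, seed, configuration hash and package version of
#' a pipeline run, for reproducibility bookkeeping.
#'
#' @param path Output JSON path.
#' @param subcommand Character scalar.
#' @param seed Integer seed used.
#' @param config Named list of parameters.
#' @return The path, invisibly.
#' @export
write_manifest <- function(path, subcommand, seed, config = list()) {
  cfg_str <- paste(names(config), vapply(config, function(x)
    paste(as.character(x), collapse = ","), character(1)),
    sep = "=", collapse = ";")
  manifest <- list(
    tool = "med12scan",
    version = as.character(utils::packageVersion("med12scan")),
    subcommand = subcommand,
    seed = seed,
    config = config,
    config_hash = sprintf("%08x", sum(utf8ToInt(cfg_str) *
                                        seq_along(utf8ToInt(cfg_str))) %% 4294967291),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
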