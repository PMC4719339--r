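#' Read a log2 expression matrix from TSV
#'
#' Expects a header row of sample identifiers, a first column named
#' `probe_id`, and numeric log2 expression values. Duplicate probe or sample
#' identifiers and non-finite values are rejected.
#'
#' @param path path to a tab-separated file.
#' @return numeric matrix, probes in rows (rownames = probe ids), samples in
#'   columns (colnames = sample ids).
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1L] != "probe_id") {
    stop("expression TSV must have 'probe_id' as its first column: ", path,
         call. = FALSE)
  }
  probes <- as.character(df$probe_id)
  x <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(x) <- "double"
  rownames(x) <- probes
  validate_expression(x)
  x
}

#' @rdname read_expression_tsv
#' @param expr matrix as returned by [read_expression_tsv()].
#' @export
write_expression_tsv <- function(expr, path) {
  validate_expression(expr)
  df <- data.frame(probe_id = rownames(expr), expr,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_expression <- function(expr) {
  if (!is.matrix(expr) || !is.numeric(expr)) {
    stop("expression must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(expr)) || is.null(colnames(expr))) {
    stop("expression matrix needs probe rownames and sample colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(expr))) {
    stop("duplicate probe ids: ",
         paste(unique(rownames(expr)[duplicated(rownames(expr))])[1:3],
               collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(colnames(expr))) {
    stop("duplicate sample ids: ",
         paste(unique(colnames(expr)[duplicated(colnames(expr))])[1:3],
               collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(expr))) {
    stop("expression matrix contains non-finite values", call. = FALSE)
  }
  invisible(TRUE)
}

#' Read and write gene-set GMT files
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then member identifiers.
#'
#' @param path file path.
#' @return named list of character vectors (unique members, input order).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 3L) {
      stop("malformed GMT line ", i, " in ", path,
           " (need name, description and >=1 member)", call. = FALSE)
    }
    nm <- parts[1L]
    if (nm %in% names(sets)) {
      stop("duplicate gene-set name '", nm, "' at GMT line ", i, call. = FALSE)
    }
    sets[[nm]] <- unique(parts[-(1:2)])
  }
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @param descriptions optional character vector of per-set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop("every gene set must be named", call. = FALSE)
  }
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a clinical visit table from CSV
#'
#' Expected columns: `patient_id`, `visit`, `tjc28`, `sjc28`, `crp_mg_l`,
#' `pga_cm`, `ega_cm`. Component bounds are validated row by row; an
#' out-of-range value is reported with its row number and field name.
#'
#' @param path file path.
#' @return data.frame of visits.
#' @export
read_clinical_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "visit", "tjc28", "sjc28", "crp_mg_l",
            "pga_cm", "ega_cm")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("clinical CSV ", path, " lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  validate_visit(df$tjc28, df$sjc28, df$crp_mg_l, df$pga_cm, df$ega_cm)
  if (anyDuplicated(df[c("patient_id", "visit")])) {
    stop("duplicate patient_id/visit rows in ", path, call. = FALSE)
  }
  df
}

#' @rdname read_clinical_csv
#' @param clinical data.frame of visits.
#' @export
write_clinical_csv <- function(clinical, path) {
  utils::write.csv(clinical, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a two-condition experiment design table
#'
#' CSV with columns `sample_id`, `condition` (`control` / `perturbed`) and an
#' optional `pair_id` linking one control to one perturbed sample.
#'
#' @param path file path.
#' @return data.frame with validated design columns.
#' @export
read_design_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "condition")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("design CSV ", path, " lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(df$condition), c("control", "perturbed"))
  if (length(bad)) {
    stop("unknown condition label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample ids in design CSV ", path, call. = FALSE)
  }
  df
}

#' @rdname read_design_csv
#' @param design data.frame with `sample_id`, `condition`, optional `pair_id`.
#' @export
write_design_csv <- function(design, path) {
  utils::write.csv(design, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a run manifest recording configuration and file checksums
#'
#' The manifest captures the package version, the configuration used, the
#' root seed and an MD5 checksum per input/output file, which is sufficient
#' to verify byte-identical reproduction of a run. No timestamp is recorded
#' so that repeated runs of the same configuration produce identical
#' manifests.
#'
#' @param config list: the configuration the run used.
#' @param files character vector of file paths to checksum.
#' @param path output path for the manifest JSON.
#' @param seed the root seed of the run.
#' @return invisibly, the manifest list.
#' @export
write_run_manifest <- function(config, files, path, seed = NULL) {
  files <- files[file.exists(files)]
  sums <- tools::md5sum(files)
  names(sums) <- basename(files)
  manifest <- list(
    tool = "synovact",
    version = as.character(utils::packageVersion("synovact")),
    seed = seed,
    config = config,
    checksums = as.list(sums)
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(manifest)
}
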