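#' Read a gene-level copy-number call matrix
#'
#' Tab-delimited file: header row of sample names, first column gene IDs,
#' cells drawn from the tokens `NEUTRAL`, `GAIN`, `LOSS`, `LOH`, `GAIN+LOH`,
#' `LOSS+LOH`. A bare `LOH` token means copy-neutral LOH.
#'
#' @param path file path.
#' @return A [cn_calls] object.
#' @export
read_cn_calls <- function(path) {
  df <- read_tsv_matrix(path, what = "character")
  state <- df
  loh <- matrix(FALSE, nrow(df), ncol(df), dimnames = dimnames(df))
  token_state <- c(NEUTRAL = "NEUTRAL", GAIN = "GAIN", LOSS = "LOSS",
                   LOH = "NEUTRAL", `GAIN+LOH` = "GAIN", `LOSS+LOH` = "LOSS")
  token_loh <- c(NEUTRAL = FALSE, GAIN = FALSE, LOSS = FALSE,
                 LOH = TRUE, `GAIN+LOH` = TRUE, `LOSS+LOH` = TRUE)
  bad <- matrix(!(df %in% names(token_state)), nrow(df), ncol(df))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("%s: unknown call token '%s' at gene '%s', sample '%s'",
                 path, df[idx[1L], idx[2L]], rownames(df)[idx[1L]],
                 colnames(df)[idx[2L]]))
  }
  state[] <- token_state[df]
  loh[] <- token_loh[df]
  cn_calls(state, loh)
}

#' Write a copy-number call matrix
#'
#' Inverse of [read_cn_calls()]; round-trips exactly.
#'
#' @param calls a [cn_calls] object.
#' @param path output file path.
#' @export
write_cn_calls <- function(calls, path) {
  tok <- calls$state
  tok[calls$loh & tok != "NEUTRAL"] <- paste0(tok[calls$loh & tok != "NEUTRAL"], "+LOH")
  tok[calls$loh & calls$state == "NEUTRAL"] <- "LOH"
  write_tsv_matrix(tok, path)
  invisible(path)
}

#' Read a normalized expression matrix
#'
#' Tab-delimited numeric matrix (log2 scale expected), gene IDs in the first
#' column, sample names in the header. Missing or non-numeric cells are
#' rejected with their coordinates; inputs are assumed complete.
#'
#' @param path file path.
#' @return A numeric matrix validated by [expression_matrix()].
#' @export
read_expression <- function(path) {
  df <- read_tsv_matrix(path, what = "character")
  values <- suppressWarnings(array(as.numeric(df), dim = dim(df),
                                   dimnames = dimnames(df)))
  bad <- is.na(values)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("%s: non-numeric expression value '%s' at gene '%s', sample '%s'",
                 path, df[idx[1L], idx[2L]], rownames(df)[idx[1L]],
                 colnames(df)[idx[2L]]))
  }
  expression_matrix(values)
}

#' Write an expression matrix
#'
#' Uses full precision (`format(..., digits = 17)`) so that
#' [read_expression()] round-trips bit-exactly.
#'
#' @param values numeric matrix.
#' @param path output file path.
#' @export
write_expression <- function(values, path) {
  values <- expression_matrix(values)
  chr <- array(vapply(values, function(v) format(v, digits = 17), character(1)),
               dim = dim(values), dimnames = dimnames(values))
  write_tsv_matrix(chr, path)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member genes, tab-separated.
#' Duplicate members within a set are de-duplicated; set order is preserved.
#'
#' @param path file path.
#' @return A [gene_set_collection].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(gene_set_collection(list()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short)) {
    stop(sprintf("%s: line %d has fewer than 3 tab-separated fields", path, short[1L]))
  }
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- vapply(fields, `[[`, character(1), 1L)
  gene_set_collection(sets, vapply(fields, `[[`, character(1), 2L))
}

#' Write gene sets in GMT format
#'
#' @param sets a [gene_set_collection].
#' @param path output file path.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "descriptions")
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], desc[[i]], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a long-format IC50 table
#'
#' Tab-delimited with header `drug`, `sample`, `ic50_uM`, `censored` (0/1).
#'
#' @param path file path.
#' @return An [ic50_table].
#' @export
read_ic50 <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("drug", "sample", "ic50_uM", "censored")
  if (!all(need %in% names(df))) {
    stop(path, ": IC50 table must have columns ", paste(need, collapse = ", "))
  }
  ic50_table(df$drug, df$sample, df$ic50_uM, df$censored %in% c(1, "1", TRUE, "TRUE"))
}

#' Write a long-format IC50 table
#'
#' @param tab an [ic50_table].
#' @param path output file path.
#' @export
write_ic50 <- function(tab, path) {
  out <- data.frame(drug = tab$drug, sample = tab$sample,
                    ic50_uM = vapply(tab$ic50_uM, format, character(1), digits = 17),
                    censored = as.integer(tab$censored))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a flat key = value configuration file
#'
#' Lines of the form `key = value` (or `key: value`); `#` starts a comment.
#' Recognized keys are the arguments of [pipeline_config()]; unknown keys are
#' an error. `sam_s0_percentiles` takes a comma-separated list.
#'
#' @param path file path.
#' @param base configuration to override; defaults to [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_config <- function(path, base = pipeline_config()) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  overrides <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_]+)\\s*[=:]\\s*(.*)$", ln))[[1]]
    if (length(m) != 3L) stop(path, ": cannot parse config line: ", ln)
    key <- m[2]; val <- trimws(m[3])
    if (!key %in% names(base)) stop(path, ": unknown config key '", key, "'")
    overrides[[key]] <- if (key == "sam_s0_percentiles") {
      as.numeric(strsplit(val, ",")[[1]])
    } else as.numeric(val)
  }
  do.call(pipeline_config, utils::modifyList(unclass(base), overrides))
}

# -- internal TSV helpers ----------------------------------------------------

# Strict matrix reader: rejects ragged rows and duplicate gene IDs, keeps
# cells as character so callers can report coordinates of bad values.
read_tsv_matrix <- function(path, what = "character") {
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(unique(nf)) > 1L) {
    stop(sprintf("%s: ragged rows (field counts %s)", path,
                 paste(unique(nf), collapse = ", ")))
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character", quote = "")
  if (ncol(df) < 2L) stop(path, ": expected a gene-ID column plus sample columns")
  genes <- df[[1L]]
  if (anyDuplicated(genes)) {
    stop(sprintf("%s: duplicate gene identifier '%s'", path,
                 genes[duplicated(genes)][1L]))
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- genes
  m
}

write_tsv_matrix <- function(m, path, id_header = "gene") {
  out <- cbind(rownames(m), m)
  colnames(out) <- c(id_header, colnames(m))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
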