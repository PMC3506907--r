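## Lightweight stderr logging. Verbosity via options(grnibench.verbose = FALSE).
grn_log <- function(...) {
  if (isTRUE(getOption("grnibench.verbose", TRUE))) {
    message("[grnibench] ", ...)
  }
  invisible(NULL)
}

#' Read an expression matrix from tab-separated text
#'
#' Two dialects are understood. `"genes_by_samples"`: first column gene
#' identifiers, header row sample identifiers. `"dream_rowsamples"`: the
#' dialect of challenge-style files — header row gene identifiers, each
#' subsequent row one sample. Either way the result is oriented genes x
#' samples with gene order preserved.
#'
#' @param path Path to a UTF-8 tab-separated text file.
#' @param dialect `"genes_by_samples"` or `"dream_rowsamples"`.
#' @param design Design label to attach, default `"multifactorial"`.
#' @return A [grn_expression()].
#' @export
read_expression <- function(path, dialect = c("genes_by_samples", "dream_rowsamples"),
                            design = "multifactorial") {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) stop("expression file needs a header and at least one data row")
  cells <- strsplit(lines, "\t", fixed = TRUE)
  if (dialect == "genes_by_samples") {
    header <- cells[[1]]
    sample_ids <- header[-1]
    width <- length(header)
    gene_ids <- character(length(cells) - 1L)
    mat <- matrix(NA_real_, length(cells) - 1L, length(sample_ids))
    for (i in 2:length(cells)) {
      row <- cells[[i]]
      if (length(row) != width) stop("ragged row at line ", i)
      gene_ids[i - 1L] <- row[1]
      vals <- suppressWarnings(as.numeric(row[-1]))
      if (anyNA(vals)) stop("non-numeric cell at line ", i)
      mat[i - 1L, ] <- vals
    }
    if (anyDuplicated(gene_ids)) stop("duplicate gene identifiers in ", path)
    dimnames(mat) <- list(gene_ids, sample_ids)
  } else {
    gene_ids <- cells[[1]]
    if (gene_ids[1] == "") gene_ids <- gene_ids[-1]
    if (anyDuplicated(gene_ids)) stop("duplicate gene identifiers in ", path)
    n_s <- length(cells) - 1L
    mat <- matrix(NA_real_, length(gene_ids), n_s,
                  dimnames = list(gene_ids, paste0("S", seq_len(n_s))))
    for (i in 2:length(cells)) {
      row <- cells[[i]]
      if (length(row) == length(gene_ids) + 1L) row <- row[-1] # leading sample label
      if (length(row) != length(gene_ids)) stop("ragged row at line ", i)
      vals <- suppressWarnings(as.numeric(row))
      if (anyNA(vals)) stop("non-numeric cell at line ", i)
      mat[, i - 1L] <- vals
    }
  }
  grn_expression(mat, design = design)
}

#' Write an expression matrix as tab-separated text
#'
#' @param data A `grn_expression`.
#' @param path Output path.
#' @inheritParams read_expression
#' @return `path`, invisibly.
#' @export
write_expression <- function(data, path, dialect = c("genes_by_samples", "dream_rowsamples")) {
  dialect <- match.arg(dialect)
  m <- data$values
  if (dialect == "genes_by_samples") {
    header <- paste(c("gene", colnames(m)), collapse = "\t")
    body <- vapply(seq_len(nrow(m)), function(i) {
      paste(c(rownames(m)[i], format(m[i, ], trim = TRUE, digits = 15)), collapse = "\t")
    }, character(1))
  } else {
    header <- paste(rownames(m), collapse = "\t")
    body <- vapply(seq_len(ncol(m)), function(j) {
      paste(format(m[, j], trim = TRUE, digits = 15), collapse = "\t")
    }, character(1))
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a gold-standard edge list
#'
#' Expects 3-column tab-separated rows `regulator<TAB>target<TAB>label` with
#' label 1 (true interaction) or 0 (explicit non-interaction). Label-1 rows
#' become network edges; label-0 rows are kept as explicit negatives in the
#' `"negatives"` attribute. Evaluation is closed-world by default, so absent
#' pairs count as negatives regardless.
#'
#' @param path Path to the edge-list file.
#' @param universe Character vector of all gene identifiers; rows referencing
#'   genes outside it are an error.
#' @return A `grn_network` over `universe`; TFs are the genes that appear as
#'   regulators.
#' @export
read_gold_standard <- function(path, universe) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  cells <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(cells) != 3L)
  if (length(bad)) stop("expected 3 tab-separated columns at line ", bad[1])
  reg <- vapply(cells, `[[`, character(1), 1L)
  tgt <- vapply(cells, `[[`, character(1), 2L)
  lab <- vapply(cells, `[[`, character(1), 3L)
  if (!all(lab %in% c("0", "1"))) {
    stop("label column must be 0 or 1 (line ",
         which(!lab %in% c("0", "1"))[1], ")")
  }
  unknown <- setdiff(c(reg, tgt), universe)
  if (length(unknown)) stop("gene(s) outside universe: ",
                            paste(unique(unknown), collapse = ", "))
  if (any(reg == tgt)) stop("self-loop row at line ", which(reg == tgt)[1])
  pos <- lab == "1"
  tf <- setNames(universe %in% reg, universe)
  edges <- data.frame(regulator = reg[pos], target = tgt[pos],
                      sign = NA_character_, weight = 1, stringsAsFactors = FALSE)
  net <- grn_network(universe, tf, edges)
  attr(net, "negatives") <- data.frame(regulator = reg[!pos], target = tgt[!pos],
                                       stringsAsFactors = FALSE)
  net
}

#' Write a network or score matrix as an edge file
#'
#' `"tsv_edges"` writes columns `regulator, target, weight, condition,
#' evidence`; `"sif"` writes Cytoscape simple-interaction lines
#' `regulator<TAB>reg<TAB>target`. For a score matrix, entries with positive
#' score become edges.
#'
#' @param x A `grn_network` or `grn_scores`.
#' @param path Output path.
#' @param format `"tsv_edges"` or `"sif"`.
#' @param condition Optional per-edge (or scalar) condition label.
#' @param evidence Optional per-edge (or scalar) evidence label.
#' @return `path`, invisibly.
#' @export
write_network <- function(x, path, format = c("tsv_edges", "sif"),
                          condition = NA, evidence = NA) {
  format <- match.arg(format)
  if (inherits(x, "grn_scores")) {
    el <- score_edge_list(x)
  } else if (inherits(x, "grn_network")) {
    el <- x$edges[c("regulator", "target", "weight")]
  } else stop("x must be a grn_network or grn_scores")
  if (format == "sif") {
    writeLines(paste(el$regulator, "reg", el$target, sep = "\t"), path)
    return(invisible(path))
  }
  el$condition <- rep_len(as.character(condition), max(nrow(el), 1))[seq_len(nrow(el))]
  el$evidence <- rep_len(as.character(evidence), max(nrow(el), 1))[seq_len(nrow(el))]
  header <- "regulator\ttarget\tweight\tcondition\tevidence"
  body <- if (nrow(el)) {
    paste(el$regulator, el$target,
          format(el$weight, trim = TRUE, digits = 15),
          el$condition, el$evidence, sep = "\t")
  } else character()
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read back a tsv_edges file written by [write_network()]
#' @param path Path to a tsv_edges file.
#' @return Data frame with the five edge columns.
#' @export
read_edge_table <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = c("character", "character", "numeric",
                                   "character", "character"))
}

#' Write a regulator-switch manifest as tab-separated text
#' @param manifest The manifest data frame from [make_condition_pair()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_switch_manifest <- function(manifest, path) {
  utils::write.table(manifest, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a `key: value` pipeline configuration file
#'
#' Minimal structured config reader: one `key: value` pair per line, `#`
#' comments allowed. Keys not present in `defaults` are rejected, and the
#' fully resolved configuration is logged, so every run records exactly the
#' settings in force.
#'
#' @param path Path to the config file.
#' @param defaults Named list of known keys and default values; values are
#'   coerced to the default's type.
#' @return Named list: defaults overridden by the file.
#' @export
read_config <- function(path, defaults) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  cfg <- defaults
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(m) != 3) stop("malformed config line: ", ln)
    key <- trimws(m[2]); val <- trimws(m[3])
    if (!key %in% names(defaults)) stop("unknown config key: ", key)
    proto <- defaults[[key]]
    cfg[[key]] <- if (is.numeric(proto)) as.numeric(val)
                  else if (is.logical(proto)) as.logical(val)
                  else val
  }
  grn_log("config: ", paste(names(cfg), vapply(cfg, format, character(1)),
                            sep = "=", collapse = " "))
  cfg
}
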