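#' Study design table
#'
#' Builds and validates the per-sample annotation table that every other
#' operation keys on.  A design assigns each library a biological group, a
#' replicate index and a batch label, optionally a library-preparation
#' protocol, a timepoint in months and a packaging-unit label (the latter two
#' only matter for stability and homogeneity studies).
#'
#' @param x a data.frame with columns \code{sample}, \code{group},
#'   \code{replicate}, \code{batch} and optionally \code{protocol},
#'   \code{timepoint}, \code{unit}.  Unknown columns are preserved as opaque
#'   annotations.
#' @return a \code{study_design} object (a validated data.frame).
#' @export
study_design <- function(x) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  required <- c("sample", "group", "replicate", "batch")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0L) {
    stop("design is missing required column(s): ",
         paste(missing_cols, collapse = ", "),
         " (required: ", paste(required, collapse = ", "), ")")
  }
  x$sample    <- as.character(x$sample)
  x$group     <- as.character(x$group)
  x$batch     <- as.character(x$batch)
  x$replicate <- as.integer(x$replicate)
  if (anyNA(x$replicate) || any(x$replicate < 1L)) {
    stop("replicate indices must be positive integers")
  }
  if (anyDuplicated(x$sample)) {
    stop("duplicate sample id(s): ",
         paste(unique(x$sample[duplicated(x$sample)]), collapse = ", "))
  }
  key <- paste(x$group, x$replicate, x$batch, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- x[duplicated(key), , drop = FALSE][1L, ]
    stop("duplicate (group, replicate, batch) triple: (",
         dup$group, ", ", dup$replicate, ", ", dup$batch, ")")
  }
  if ("timepoint" %in% names(x)) {
    x$timepoint <- as.numeric(x$timepoint)
    if (any(!is.na(x$timepoint) & x$timepoint < 0)) {
      stop("timepoints (months) must be non-negative")
    }
  }
  rownames(x) <- NULL
  class(x) <- c("study_design", "data.frame")
  x
}

#' @export
print.study_design <- function(x, ...) {
  s <- tryCatch(summarize_design(x), error = function(e) NULL)
  cat("Study design:", nrow(x), "samples\n")
  if (!is.null(s)) {
    cat("  groups (m=", s$m, "): ",
        paste(names(s$n_per_group), " (n=", s$n_per_group, ")",
              sep = "", collapse = ", "), "\n", sep = "")
    cat("  batches:", paste(s$batches, collapse = ", "), "\n")
    cat("  sample pairs: between-group", s$n_between_pairs,
        "/ within-group", s$n_within_pairs, "\n")
  }
  invisible(x)
}

#' Read a study design from a delimited file
#'
#' @param path path to a TSV (or CSV) file with header columns
#'   \code{sample}, \code{group}, \code{replicate}, \code{batch} and optional
#'   \code{protocol}, \code{timepoint}, \code{unit}.
#' @param sep field separator, tab by default.
#' @return a \code{study_design}.
#' @export
read_study_design <- function(path, sep = "\t") {
  x <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE, check.names = FALSE,
                         quote = "", comment.char = "")
  study_design(x)
}

#' Read an expression matrix from a delimited file
#'
#' Reads a gene-by-sample (or sample-by-gene) table of non-negative values.
#' Internally genes are always rows, whatever the file orientation.
#'
#' @param path path to a delimited text file whose first column (or first
#'   row, for \code{samples-in-rows}) holds identifiers.
#' @param layer \code{"values"} for continuous abundances (FPKM-like) or
#'   \code{"counts"} for integer read counts.
#' @param orientation \code{"genes-in-rows"} (default) or
#'   \code{"samples-in-rows"}.
#' @param sep field separator, tab by default (use \code{","} for CSV).
#' @return a numeric matrix, genes in rows, samples in columns.
#' @export
read_expression_matrix <- function(path,
                                   layer = c("values", "counts"),
                                   orientation = c("genes-in-rows",
                                                   "samples-in-rows"),
                                   sep = "\t") {
  layer <- match.arg(layer)
  orientation <- match.arg(orientation)
  x <- utils::read.table(path, header = TRUE, sep = sep, row.names = NULL,
                         stringsAsFactors = FALSE, check.names = FALSE,
                         quote = "", comment.char = "",
                         colClasses = "character")
  ids <- x[[1L]]
  if (anyDuplicated(ids)) {
    stop("duplicate identifier(s) in first column of ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  body <- x[, -1L, drop = FALSE]
  m <- matrix(NA_real_, nrow = nrow(body), ncol = ncol(body),
              dimnames = list(ids, colnames(body)))
  for (j in seq_len(ncol(body))) {
    v <- suppressWarnings(as.numeric(body[[j]]))
    bad <- which(is.na(v))
    if (length(bad) > 0L) {
      stop("non-numeric or missing cell at row '", ids[bad[1L]],
           "', column '", colnames(body)[j], "' in ", path)
    }
    m[, j] <- v
  }
  if (orientation == "samples-in-rows") m <- t(m)
  if (any(m < 0)) {
    idx <- which(m < 0, arr.ind = TRUE)[1L, ]
    stop("negative value at gene '", rownames(m)[idx[1L]], "', sample '",
         colnames(m)[idx[2L]], "'")
  }
  if (layer == "counts" && any(abs(m - round(m)) > 1e-8)) {
    idx <- which(abs(m - round(m)) > 1e-8, arr.ind = TRUE)[1L, ]
    stop("counts layer must be integer; offending cell at gene '",
         rownames(m)[idx[1L]], "', sample '", colnames(m)[idx[2L]], "'")
  }
  m
}

#' Expression study: matrices bound to a design
#'
#' Binds a continuous abundance matrix (and optionally an integer count
#' matrix) to a \code{\link{study_design}}.  Matrix columns are reordered to
#' the design's sample order so all downstream math shares one canonical
#' ordering.
#'
#' @param values gene x sample matrix of non-negative continuous abundances.
#' @param design a \code{study_design} whose samples exactly match
#'   \code{colnames(values)}.
#' @param counts optional gene x sample matrix of non-negative integer read
#'   counts with the same dimnames as \code{values}.
#' @return an \code{expression_study} object.
#' @export
expression_study <- function(values, design, counts = NULL) {
  if (!inherits(design, "study_design")) design <- study_design(design)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values matrix must carry gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate gene identifier(s): ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  }
  missing_in_matrix <- setdiff(design$sample, colnames(values))
  if (length(missing_in_matrix) > 0L) {
    stop("sample(s) in design but absent from matrix: ",
         paste(missing_in_matrix, collapse = ", "))
  }
  extra <- setdiff(colnames(values), design$sample)
  if (length(extra) > 0L) {
    stop("sample(s) in matrix but absent from design: ",
         paste(extra, collapse = ", "))
  }
  values <- values[, design$sample, drop = FALSE]
  if (any(values < 0)) stop("expression values must be non-negative")
  if (!is.null(counts)) {
    if (!identical(dim(counts), dim(values)) ||
        !setequal(colnames(counts), design$sample) ||
        !identical(sort(rownames(counts)), sort(rownames(values)))) {
      stop("counts must share genes and samples with values")
    }
    counts <- counts[rownames(values), design$sample, drop = FALSE]
    if (any(counts < 0)) stop("counts must be non-negative")
  }
  structure(list(values = values, counts = counts, design = design),
            class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat("Expression study:", nrow(x$values), "genes x",
      ncol(x$values), "samples",
      if (!is.null(x$counts)) "(values + counts)" else "(values only)", "\n")
  print(x$design)
  invisible(x)
}

#' @export
dim.expression_study <- function(x) dim(x$values)

#' Summarize a study design
#'
#' Reports the group/replicate structure and the sample-pair bookkeeping that
#' drives the SNR prefactor: the count of between-group sample pairs
#' (C(N,2) minus the within-group pairs) and of within-group pairs
#' (sum over groups of C(n_g, 2)).  For the canonical 4-group x 3-replicate
#' batch these are 54 and 12.
#'
#' @param design a \code{study_design}.
#' @return a list with \code{m}, \code{n_per_group}, \code{batches},
#'   \code{n_between_pairs}, \code{n_within_pairs}.
#' @export
summarize_design <- function(design) {
  if (!inherits(design, "study_design")) design <- study_design(design)
  groups <- unique(design$group)
  if (length(groups) < 2L) {
    stop("SNR undefined: design must contain at least 2 groups")
  }
  n_per_group <- vapply(groups, function(g) sum(design$group == g),
                        integer(1L))
  n_total <- nrow(design)
  within <- sum(choose(n_per_group, 2L))
  between <- choose(n_total, 2L) - within
  list(m = length(groups),
       n_per_group = n_per_group,
       batches = unique(design$batch),
       n_between_pairs = as.integer(between),
       n_within_pairs = as.integer(within))
}

## ---- reference dataset container + TSV serialization -----------------------

.ref_columns <- c("gene", "pair", "log2fc_ref", "n_batches", "n_up", "n_down",
                  "u_char", "u_bb", "u_s", "u_c", "k", "U", "deg_label")

#' Reference dataset of ratio-based fold changes
#'
#' One record per (gene, ordered group pair): the consensus reference log2
#' fold change, cross-batch vote counts, the uncertainty budget (relative
#' characterization, between-unit, stability, combined and expanded
#' uncertainties) and the consensus differential-expression label.
#'
#' @param x a data.frame with columns \code{gene}, \code{pair},
#'   \code{log2fc_ref}, \code{n_batches}, \code{n_up}, \code{n_down},
#'   \code{u_char}, \code{u_bb}, \code{u_s}, \code{u_c}, \code{k}, \code{U},
#'   \code{deg_label}.  Uncertainty fields may be NA before the budget is
#'   computed.
#' @param validate check the expanded-uncertainty identity \code{U = k * u_c}
#'   and label consistency.
#' @return a \code{reference_dataset} (data.frame subclass).
#' @export
reference_dataset <- function(x, validate = TRUE) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.ref_columns, names(x))
  if (length(missing_cols) > 0L) {
    stop("reference dataset missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  x <- x[, .ref_columns]
  key <- paste(x$gene, x$pair, sep = "\r")
  if (anyDuplicated(key)) {
    stop("reference dataset has more than one record per (gene, pair)")
  }
  bad_label <- setdiff(unique(x$deg_label),
                       c("up", "down", "non-DEG", "unassessed"))
  if (length(bad_label) > 0L) {
    stop("invalid deg_label value(s): ", paste(bad_label, collapse = ", "))
  }
  if (validate) {
    have_u <- !is.na(x$U) & !is.na(x$u_c) & !is.na(x$k)
    off <- have_u & abs(x$U - x$k * x$u_c) >
      1e-8 * pmax(abs(x$U), 1)
    if (any(off)) {
      stop("expanded uncertainty violates U = k * u_c for gene(s): ",
           paste(utils::head(x$gene[off], 5L), collapse = ", "))
    }
  }
  rownames(x) <- NULL
  class(x) <- c("reference_dataset", "data.frame")
  x
}

#' @export
print.reference_dataset <- function(x, ...) {
  cat("Reference dataset:", nrow(x), "records,",
      length(unique(x$pair)), "group pair(s)\n")
  tab <- table(factor(x$deg_label,
                      levels = c("up", "down", "non-DEG", "unassessed")))
  cat("  labels:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Write / read a reference dataset as TSV
#'
#' Numeric fields are serialized with 17 significant digits so a write/read
#' round trip is lossless to within 1e-12 relative error.
#'
#' @param ref a \code{reference_dataset}.
#' @param path output (input) file path.
#' @return \code{write_reference_dataset} returns \code{path} invisibly;
#'   \code{read_reference_dataset} returns a validated
#'   \code{reference_dataset}.
#' @export
write_reference_dataset <- function(ref, path) {
  ref <- reference_dataset(ref)
  out <- ref
  num <- vapply(out, is.numeric, logical(1L))
  for (j in which(num)) {
    out[[j]] <- ifelse(is.na(out[[j]]), "NA",
                       sprintf("%.17g", out[[j]]))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_reference_dataset
#' @export
read_reference_dataset <- function(path) {
  n_fields <- utils::count.fields(path, sep = "\t", quote = "",
                                  comment.char = "")
  if (length(n_fields) == 0L) stop("empty reference file: ", path)
  bad <- which(n_fields != n_fields[1L])
  if (length(bad) > 0L) {
    stop("malformed reference file ", path, ": line ", bad[1L],
         " has ", n_fields[bad[1L]], " fields, expected ", n_fields[1L])
  }
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, check.names = FALSE,
                         quote = "", comment.char = "",
                         na.strings = "NA")
  reference_dataset(x)
}

#' Cost overhead of in-batch reference profiles
#'
#' When a batch of \code{n_total} libraries carries \code{n_reference}
#' reference-material profiles used as ratio denominators, the added cost per
#' study sample is \code{n_reference / (n_total - n_reference)}.  Four
#' reference profiles in a 96-library batch cost about 4.3\% extra.
#'
#' @param n_reference number of reference-profile libraries per batch.
#' @param n_total total libraries in the batch.
#' @return overhead as a percentage.
#' @export
denominator_overhead <- function(n_reference, n_total) {
  if (n_reference <= 0 || n_total <= n_reference) {
    stop("need 0 < n_reference < n_total")
  }
  100 * n_reference / (n_total - n_reference)
}

#' Fraction of annotated genes detected
#'
#' @param n_detected detected-gene count(s), e.g. per sample group.
#' @param n_annotated total annotated genes in the gene model.
#' @return percentage(s) of annotated genes detected.
#' @export
detected_fraction <- function(n_detected, n_annotated) {
  if (n_annotated <= 0) stop("n_annotated must be positive")
  100 * n_detected / n_annotated
}
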