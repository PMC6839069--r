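#' Validate a per-locus case table
#'
#' The input format for all fitting functions is one row per observed
#' locus: for each patient (case), the loci mutated in at least one of
#' the two tumors.  A locus is *shared* when mutated in both tumors and
#' *private* when mutated in exactly one.  Required columns:
#'
#' * `case_id` — case label (character or integer);
#' * `locus_id` — locus label, unique within a case;
#' * `gene_label` — optional free-text annotation (may be `NA`);
#' * `p` — occurrence probability of the mutation in a tumor of this
#'   cancer type, strictly inside (0, 1);
#' * `in_tumor1`, `in_tumor2` — 0/1 presence flags; at least one must
#'   be 1 (a locus mutated in neither tumor carries no information and
#'   is rejected).
#'
#' @param x A data frame with the columns above.
#' @return A validated tibble with the six canonical columns, original
#'   row order preserved.
#' @examples
#' as_case_table(tibble::tibble(
#'   case_id = "a", locus_id = c("l1", "l2"), gene_label = NA,
#'   p = c(0.001, 0.137), in_tumor1 = c(1, 1), in_tumor2 = c(0, 1)
#' ))
#' @export
as_case_table <- function(x) {
  stopifnot(is.data.frame(x))
  need <- c("case_id", "locus_id", "p", "in_tumor1", "in_tumor2")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols)) {
    stop("case table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  x <- tibble::as_tibble(x)
  if (!"gene_label" %in% names(x)) x$gene_label <- NA_character_
  x <- dplyr::select(x, "case_id", "locus_id", "gene_label", "p",
                     "in_tumor1", "in_tumor2")
  line <- seq_len(nrow(x))
  bad <- which(!is.finite(x$p) | x$p <= 0 | x$p >= 1)
  if (length(bad)) {
    stop("`p` must lie strictly in (0, 1); offending row(s): ",
         paste(head(bad, 5L), collapse = ", "))
  }
  if (!all(x$in_tumor1 %in% c(0, 1)) || !all(x$in_tumor2 %in% c(0, 1))) {
    stop("`in_tumor1`/`in_tumor2` must be 0 or 1")
  }
  bad <- which(x$in_tumor1 == 0 & x$in_tumor2 == 0)
  if (length(bad)) {
    stop("locus mutated in neither tumor is not informative; ",
         "offending row(s): ", paste(head(bad, 5L), collapse = ", "))
  }
  dup <- duplicated(x[, c("case_id", "locus_id")])
  if (any(dup)) {
    stop("duplicate (case_id, locus_id) pair(s); offending row(s): ",
         paste(head(line[dup], 5L), collapse = ", "))
  }
  x
}

#' Read or write a per-locus case table (TSV)
#'
#' `read_case_table()` reads a tab-separated file with header
#' `case_id, locus_id, gene_label, p, in_tumor1, in_tumor2` and
#' validates it (see [as_case_table()]); validation failures report the
#' offending file line.  `write_case_table()` writes the same format;
#' a read/write round trip preserves content and row order.
#'
#' @param path File path.
#' @return `read_case_table()` returns a validated tibble;
#'   `write_case_table()` returns `x` invisibly.
#' @export
read_case_table <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(
                         case_id = readr::col_character(),
                         locus_id = readr::col_character(),
                         gene_label = readr::col_character(),
                         p = readr::col_double(),
                         in_tumor1 = readr::col_integer(),
                         in_tumor2 = readr::col_integer()
                       ))
  expect_names <- c("case_id", "locus_id", "gene_label", "p",
                    "in_tumor1", "in_tumor2")
  if (!identical(names(x), expect_names)) {
    stop("header of ", path, " must be exactly: ",
         paste(expect_names, collapse = ", "))
  }
  out <- tryCatch(as_case_table(x), error = function(e) {
    # +1: account for the header line of the file
    stop(conditionMessage(e), " (add 1 for the header line of ", path, ")",
         call. = FALSE)
  })
  out
}

#' @rdname read_case_table
#' @param x A case table (see [as_case_table()]).
#' @export
write_case_table <- function(x, path) {
  x <- as_case_table(x)
  readr::write_tsv(x, path, progress = FALSE)
  invisible(x)
}

# Internal flat representation used by all numerics: loci as parallel
# vectors plus a locus -> case index, and the per-case independence
# log-likelihood (fixed in the parameters).  `case_ids` may list cases
# with no loci; they contribute log-likelihood 0.
compile_case_data <- function(x, case_ids = NULL) {
  x <- as_case_table(x)
  ids_in_table <- unique(x$case_id)
  if (is.null(case_ids)) {
    case_ids <- ids_in_table
  } else {
    case_ids <- unique(case_ids)
    orphan <- setdiff(as.character(ids_in_table), as.character(case_ids))
    if (length(orphan)) {
      stop("`case_ids` must cover every case present in the table; ",
           "missing: ", paste(head(orphan, 5L), collapse = ", "))
    }
  }
  idx <- match(as.character(x$case_id), as.character(case_ids))
  shared <- x$in_tumor1 == 1 & x$in_tumor2 == 1
  n <- length(case_ids)
  lI_loc <- ifelse(shared,
                   log(x$p) - log(2 - x$p),
                   log(2) + log1p(-x$p) - log(2 - x$p))
  # sparse case-by-locus aggregator: G %*% v sums a per-locus vector (or
  # matrix) into per-case totals, with zero rows for empty cases
  G <- Matrix::sparseMatrix(i = idx, j = seq_along(idx), x = 1,
                            dims = c(n, nrow(x)))
  lI <- as.vector(G %*% lI_loc)
  n_shared <- as.vector(G %*% shared)
  list(case_ids = case_ids, n = n, p = x$p, shared = shared,
       idx = idx, G = G, lI = lI, n_shared = n_shared)
}
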