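# Digital expression (MPSS-style tag counts): tags-per-million
# normalization, presence calls, two-fold stress/hormone response calls,
# and the duplicated-pair expression-diversification matrix.

#' Normalize a tag-count matrix to tags per million (tpm)
#'
#' tpm(g, l) = count(g, l) / library total(l) x 1e6; every library column
#' then sums to one million.
#'
#' @param counts Numeric matrix (genes x libraries) of nonnegative integer
#'   tag counts with dimnames.
#' @return Matrix of tpm values with the same dimnames.
#' @export
normalize_tpm <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  totals <- colSums(counts)
  zero <- which(totals == 0)
  if (length(zero))
    stop("library with zero total tags: ",
         paste(colnames(counts)[zero], collapse = ", "), call. = FALSE)
  sweep(counts, 2, totals, "/") * 1e6
}

#' Presence calls from tpm values
#'
#' A gene is called present in a library when its tpm is at or above
#' `min_tpm` (default 1 tpm).
#'
#' @param tpm Numeric vector or matrix of tpm values.
#' @param min_tpm Presence threshold (>= 0).
#' @return Logical vector/matrix of the same shape.
#' @export
call_presence <- function(tpm, min_tpm = 1) {
  stopifnot(min_tpm >= 0)
  tpm >= min_tpm
}

#' Two-fold response call for one gene in one contrast
#'
#' Computes fold = (treatment + pseudo) / (control + pseudo) and calls
#' `"up"` when fold is at least `fold_threshold` (boundary inclusive:
#' exactly two-fold counts), `"down"` when fold is at most
#' 1/`fold_threshold`, otherwise `"none"`; `"not_assessable"` when both
#' values are below `min_tpm`.
#'
#' @param control_tpm,treatment_tpm tpm values (scalars or equal-length
#'   vectors).
#' @param fold_threshold Response threshold (> 1; default 2).
#' @param pseudo Pseudo-count in tpm added to both sides to stabilize
#'   zero-control folds (default 1; set 0 for the exact rule).
#' @param min_tpm Floor below which a contrast is not assessable.
#' @return List with `call` (character) and `fold` (numeric).
#' @export
call_response <- function(control_tpm, treatment_tpm, fold_threshold = 2,
                          pseudo = 1, min_tpm = 1) {
  stopifnot(fold_threshold > 1, pseudo >= 0)
  fold <- (treatment_tpm + pseudo) / (control_tpm + pseudo)
  call <- ifelse(control_tpm < min_tpm & treatment_tpm < min_tpm,
                 "not_assessable",
          ifelse(fold >= fold_threshold, "up",
          ifelse(fold <= 1 / fold_threshold, "down", "none")))
  list(call = call, fold = fold)
}

#' Response profiles for all genes across a contrast design
#'
#' Applies [call_response()] to every gene for every named contrast
#' (treatment library vs its control library).
#'
#' @param tpm tpm matrix (genes x libraries).
#' @param contrasts Data frame with columns `contrast`, `treatment`,
#'   `control` (library column names) and optionally `class` (condition
#'   class, e.g. `"salt"`).
#' @inheritParams call_response
#' @return Data frame with `gene`, `contrast`, `class`, `call`, `fold`.
#' @export
response_profiles <- function(tpm, contrasts, fold_threshold = 2,
                              pseudo = 1, min_tpm = 1) {
  if (is.null(contrasts$treatment) || is.null(contrasts$control))
    stop("contrasts need 'treatment' and 'control' library columns",
         call. = FALSE)
  miss <- setdiff(c(contrasts$treatment, contrasts$control), colnames(tpm))
  if (length(miss))
    stop("contrast libraries not in matrix: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (is.null(contrasts$class)) contrasts$class <- contrasts$contrast
  out <- lapply(seq_len(nrow(contrasts)), function(k) {
    cr <- call_response(tpm[, contrasts$control[k]],
                        tpm[, contrasts$treatment[k]],
                        fold_threshold, pseudo, min_tpm)
    data.frame(gene = rownames(tpm), contrast = contrasts$contrast[k],
               class = contrasts$class[k], call = unname(cr$call),
               fold = unname(cr$fold), stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Expression-diversification matrix for duplicated gene pairs
#'
#' One row per duplicated pair with a `+`/`-` column per condition class:
#' the tissues column is `+` when the two members' presence vectors differ
#' across the tissue libraries, and each stress/disease class is `+` when
#' the members' response calls differ in at least one contrast of that
#' class.
#'
#' @param pairs Data frame with `id_a`, `id_b`.
#' @param presence Logical matrix (genes x tissue libraries) from
#'   [call_presence()].
#' @param profiles Response-call data frame from [response_profiles()].
#' @param classes Character vector of class columns to report, in order;
#'   default the six-class layout `c("tissues", "salt", "drought",
#'   "cold", "xoo", "mg")` (salt/drought/cold abiotic stresses and the
#'   X. oryzae / M. grisea pathogens).
#' @return Data frame: `pair` plus one `+`/`-` column per class.
#' @export
diversification_matrix <- function(pairs, presence, profiles,
                                   classes = c("tissues", "salt", "drought",
                                               "cold", "xoo", "mg")) {
  rows <- lapply(seq_len(nrow(pairs)), function(r) {
    a <- pairs$id_a[r]; b <- pairs$id_b[r]
    for (g in c(a, b)) {
      if (!g %in% rownames(presence))
        stop("gene ", g, " missing from presence matrix", call. = FALSE)
    }
    vals <- lapply(classes, function(cl) {
      if (cl == "tissues") {
        diff <- any(presence[a, ] != presence[b, ])
      } else {
        pa <- profiles[profiles$gene == a & profiles$class == cl, ]
        pb <- profiles[profiles$gene == b & profiles$class == cl, ]
        if (nrow(pa) != nrow(pb) || nrow(pa) == 0L)
          stop("pair ", a, "/", b, " not profiled on the same contrasts ",
               "for class ", cl, call. = FALSE)
        pa <- pa[order(pa$contrast), ]; pb <- pb[order(pb$contrast), ]
        diff <- any(pa$call != pb$call)
      }
      if (diff) "+" else "-"
    })
    stats::setNames(data.frame(pair = paste(a, b, sep = "/"),
                               as.list(unlist(vals)),
                               stringsAsFactors = FALSE),
                    c("pair", classes))
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
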