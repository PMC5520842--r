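# Nei-Gojobori (1986) Ka/Ks estimation: codon-level synonymous /
# nonsynonymous site counting, minimal-pathway difference counting with
# stop-codon-avoiding pathways, Jukes-Cantor multiple-hit correction, and
# selection-regime classification.

BASES <- c("A", "C", "G", "T")

#' Standard genetic code table
#'
#' Named character vector mapping the 64 codons to amino-acid letters, with
#' `*` for stop codons. Taken from \pkg{Biostrings}; any table with the
#' same layout can be injected into the codon-level functions.
#'
#' @return Named character vector of length 64.
#' @export
standard_genetic_code <- function() {
  # cache: exported lazydata is re-fetched from disk on every `::` access
  if (is.null(.optfam_cache$genetic_code))
    .optfam_cache$genetic_code <- Biostrings::GENETIC_CODE
  .optfam_cache$genetic_code
}
.optfam_cache <- new.env(parent = emptyenv())

check_codons <- function(codons, what = "codons") {
  if (!length(codons)) stop(what, " is empty", call. = FALSE)
  if (any(nchar(codons) != 3L))
    stop(what, " must all be 3 nucleotides", call. = FALSE)
  if (any(!grepl("^[ACGT]{3}$", codons)))
    stop(what, " contain non-ACGT characters", call. = FALSE)
  invisible(codons)
}

# Fraction of synonymous sites in one codon: per position, the share of
# synonymous changes among viable (non-stop) single-base mutants.
codon_syn_sites <- function(codon, code) {
  aa <- code[[codon]]
  total <- 0
  for (pos in 1:3) {
    chars <- strsplit(codon, "")[[1]]
    syn <- 0L; viable <- 0L
    for (b in setdiff(BASES, chars[pos])) {
      mut <- chars; mut[pos] <- b
      mut_codon <- paste(mut, collapse = "")
      mut_aa <- code[[mut_codon]]
      if (mut_aa == "*") next
      viable <- viable + 1L
      if (mut_aa == aa) syn <- syn + 1L
    }
    if (viable > 0L) total <- total + syn / viable
  }
  total
}

# Average synonymous/nonsynonymous difference counts between two codons
# over all minimal mutation pathways, excluding pathways that pass through
# a stop codon (falling back to all pathways if every one is blocked).
codon_path_diffs <- function(c1, c2, code) {
  a <- strsplit(c1, "")[[1]]
  b <- strsplit(c2, "")[[1]]
  diff_pos <- which(a != b)
  nd <- length(diff_pos)
  if (nd == 0L) return(c(sd = 0, nd = 0))
  perms <- if (nd == 1L) list(diff_pos) else {
    idx <- seq_len(nd)
    ords <- if (nd == 2L) list(idx, rev(idx)) else {
      # all 6 orders of 3 positions
      do.call(c, lapply(1:3, function(i)
        lapply(setdiff(1:3, i), function(j) c(i, j, setdiff(1:3, c(i, j))))))
    }
    lapply(ords, function(o) diff_pos[o])
  }
  eval_path <- function(order) {
    cur <- a
    sd <- 0; ndn <- 0; blocked <- FALSE
    for (pos in order) {
      aa_before <- code[[paste(cur, collapse = "")]]
      cur[pos] <- b[pos]
      codon_after <- paste(cur, collapse = "")
      aa_after <- code[[codon_after]]
      if (aa_after == "*" && codon_after != c2) blocked <- TRUE
      if (aa_after == aa_before) sd <- sd + 1 else ndn <- ndn + 1
    }
    list(sd = sd, nd = ndn, blocked = blocked)
  }
  evals <- lapply(perms, eval_path)
  ok <- !vapply(evals, `[[`, logical(1), "blocked")
  if (!any(ok)) ok <- rep(TRUE, length(evals))   # all pathways blocked
  sd <- mean(vapply(evals[ok], `[[`, numeric(1), "sd"))
  ndn <- mean(vapply(evals[ok], `[[`, numeric(1), "nd"))
  c(sd = sd, nd = ndn)
}

#' Nei-Gojobori site and difference counts for a codon pair
#'
#' Counts synonymous (S) and nonsynonymous (N) sites, averaged between the
#' two sequences, and synonymous (Sd) and nonsynonymous (Nd) differences.
#' Site fractions exclude mutations to stop codons from the viable set;
#' codons differing at more than one position are resolved by averaging
#' over all minimal mutation pathways, excluding pathways through stops.
#'
#' @param codons_a,codons_b Equal-length character vectors of aligned
#'   codons (3 unambiguous nucleotides each, no stop codons).
#' @param code Genetic code table, default [standard_genetic_code()].
#' @return Named numeric vector with elements `S`, `N`, `Sd`, `Nd`;
#'   `S + N` equals three times the codon count.
#' @export
ng86_counts <- function(codons_a, codons_b, code = standard_genetic_code()) {
  check_codons(codons_a, "codons_a")
  check_codons(codons_b, "codons_b")
  if (length(codons_a) != length(codons_b))
    stop("codon vectors must have equal length", call. = FALSE)
  if (any(code[codons_a] == "*") || any(code[codons_b] == "*"))
    stop("stop codons must not be retained in the alignment", call. = FALSE)
  # site counts: memoize the per-codon fraction over the (<=61) codons seen
  uniq <- unique(c(codons_a, codons_b))
  frac <- vapply(uniq, codon_syn_sites, numeric(1), code = code)
  Sa <- sum(frac[codons_a])
  Sb <- sum(frac[codons_b])
  S <- (Sa + Sb) / 2
  N <- 3 * length(codons_a) - S
  Sd <- 0; Nd <- 0
  for (k in which(codons_a != codons_b)) {
    dd <- codon_path_diffs(codons_a[k], codons_b[k], code)
    Sd <- Sd + dd[["sd"]]
    Nd <- Nd + dd[["nd"]]
  }
  c(S = S, N = N, Sd = Sd, Nd = Nd)
}

jc_correct <- function(p, what) {
  if (p >= 0.75)
    stop("substitution proportion saturated (p >= 3/4) for ", what,
         call. = FALSE)
  -0.75 * log(1 - 4 * p / 3)
}

#' Ka and Ks from Nei-Gojobori counts
#'
#' Converts site/difference counts to proportions (ps = Sd/S, pn = Nd/N)
#' and applies the Jukes-Cantor multiple-hit correction
#' d = -(3/4) ln(1 - (4/3) p) to each. The Ka/Ks ratio is `NA` (undefined)
#' when Ks = 0.
#'
#' @param counts Named vector or list with `S`, `N`, `Sd`, `Nd`.
#' @return List with `S`, `N`, `Sd`, `Nd`, `ps`, `pn`, `Ka`, `Ks`, `ratio`.
#' @export
kaks_estimate <- function(counts) {
  counts <- as.list(counts)
  S <- counts$S; N <- counts$N; Sd <- counts$Sd; Nd <- counts$Nd
  if (is.null(S) || is.null(N) || S <= 0 || N <= 0)
    stop("S and N must be positive", call. = FALSE)
  ps <- Sd / S
  pn <- Nd / N
  Ks <- jc_correct(ps, "Ks")
  Ka <- jc_correct(pn, "Ka")
  ratio <- if (Ks > 0) Ka / Ks else NA_real_
  list(S = S, N = N, Sd = Sd, Nd = Nd, ps = ps, pn = pn,
       Ka = Ka, Ks = Ks, ratio = ratio)
}

#' Classify the selection regime from a Ka/Ks ratio
#'
#' Ka/Ks below one indicates purifying selection (deleterious changes
#' removed), above one positive selection (amino-acid change favoured),
#' and equal to one neutral evolution. An `epsilon` band around one can
#' widen the neutral zone; the default band is zero.
#'
#' @param ratio Ka/Ks value (`NA` for undefined, e.g. Ks = 0).
#' @param epsilon Half-width of the neutral band around 1 (default 0).
#' @return One of `"purifying"`, `"neutral"`, `"positive"`,
#'   `"undetermined"`.
#' @export
classify_selection <- function(ratio, epsilon = 0) {
  stopifnot(length(ratio) == 1L, epsilon >= 0)
  if (is.na(ratio)) return("undetermined")
  if (ratio < 0) stop("ratio must be nonnegative", call. = FALSE)
  if (ratio < 1 - epsilon) "purifying"
  else if (ratio > 1 + epsilon) "positive"
  else "neutral"
}

translate_codons <- function(codons, code) paste(code[codons], collapse = "")

#' Back-translate a protein alignment to codon alignments for gene pairs
#'
#' Maps each aligned residue of a protein alignment back to its source
#' codon in the corresponding CDS (a terminal stop codon is trimmed), so
#' Ka/Ks can be computed at codon level from a protein-level alignment.
#' Columns where either member is gapped, ambiguous or a stop are dropped
#' from each requested pair.
#'
#' @param protein_alignment Named character vector of gapped amino-acid
#'   rows (or `AAStringSet`).
#' @param cds Named character vector of nucleotide coding sequences (or
#'   `DNAStringSet`), names matching the alignment.
#' @param pairs Two-column data frame (or list of length-2 vectors) of
#'   sequence ids to pair; default: all unordered pairs.
#' @param code Genetic code table.
#' @return List of codon pairs, each a list with `id_a`, `id_b`,
#'   `codons_a`, `codons_b`.
#' @export
back_translate_align <- function(protein_alignment, cds, pairs = NULL,
                                 code = standard_genetic_code()) {
  if (inherits(protein_alignment, "AAStringSet"))
    protein_alignment <- stats::setNames(as.character(protein_alignment),
                                         names(protein_alignment))
  if (inherits(cds, "DNAStringSet"))
    cds <- stats::setNames(as.character(cds), names(cds))
  ids <- names(protein_alignment)
  missing_cds <- setdiff(ids, names(cds))
  if (length(missing_cds))
    stop("no CDS for: ", paste(missing_cds, collapse = ", "), call. = FALSE)

  codon_rows <- lapply(ids, function(id) {
    aa_gapped <- strsplit(protein_alignment[[id]], "")[[1]]
    aa <- aa_gapped[aa_gapped != "-"]
    seq <- toupper(cds[[id]])
    if (nchar(seq) %% 3 != 0L)
      stop("CDS length of ", id, " is not divisible by 3", call. = FALSE)
    codons <- substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3))
    if (length(codons) == length(aa) + 1L &&
        !is.na(code[codons[length(codons)]]) &&
        code[[codons[length(codons)]]] == "*")
      codons <- codons[-length(codons)]
    if (length(codons) != length(aa))
      stop("CDS of ", id, " has ", length(codons),
           " codons but the aligned protein has ", length(aa), " residues",
           call. = FALSE)
    for (k in seq_along(aa)) {
      tr <- if (grepl("^[ACGT]{3}$", codons[k])) code[[codons[k]]] else "X"
      if (aa[k] != "X" && tr != "X" && tr != aa[k])
        stop("translation mismatch for ", id, " at residue ", k,
             ": codon ", codons[k], " -> ", tr, ", alignment has ", aa[k],
             call. = FALSE)
    }
    out <- rep("---", length(aa_gapped))
    out[aa_gapped != "-"] <- codons
    out
  })
  names(codon_rows) <- ids

  if (is.null(pairs)) {
    pairs <- t(utils::combn(ids, 2))
  }
  if (is.data.frame(pairs)) pairs <- as.matrix(pairs[, 1:2])
  if (is.list(pairs) && !is.matrix(pairs)) pairs <- do.call(rbind, pairs)

  lapply(seq_len(nrow(pairs)), function(r) {
    a <- pairs[r, 1]; b <- pairs[r, 2]
    if (!a %in% ids || !b %in% ids)
      stop("pair ", a, "/", b, " not in alignment", call. = FALSE)
    ca <- codon_rows[[a]]; cb <- codon_rows[[b]]
    keep <- grepl("^[ACGT]{3}$", ca) & grepl("^[ACGT]{3}$", cb) &
      code[ca] != "*" & code[cb] != "*"
    keep[is.na(keep)] <- FALSE
    list(id_a = a, id_b = b,
         codons_a = ca[keep], codons_b = cb[keep])
  })
}

#' Ka/Ks table for a set of gene pairs
#'
#' Convenience wrapper: back-translates a protein alignment against its
#' CDS set (or takes pre-aligned equal-length CDS directly), runs
#' Nei-Gojobori counting and Jukes-Cantor correction per pair, and
#' classifies the selection regime.
#'
#' @inheritParams back_translate_align
#' @param epsilon Neutral band for [classify_selection()].
#' @return Data frame with one row per pair: ids, `S`, `N`, `Sd`, `Nd`,
#'   `Ka`, `Ks`, `ratio`, `selection`.
#' @export
kaks_pairs <- function(cds, pairs = NULL, protein_alignment = NULL,
                       code = standard_genetic_code(), epsilon = 0) {
  if (inherits(cds, "DNAStringSet"))
    cds <- stats::setNames(as.character(cds), names(cds))
  if (is.null(protein_alignment)) {
    # pre-aligned CDS path: translate each CDS to build the protein rows
    protein_alignment <- vapply(cds, function(s) {
      s <- toupper(s)
      if (nchar(s) %% 3 != 0L)
        stop("CDS length not divisible by 3", call. = FALSE)
      codons <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
      aa <- ifelse(codons == "---", "-",
                   ifelse(grepl("^[ACGT]{3}$", codons),
                          unname(code[codons]), "X"))
      if (aa[length(aa)] == "*") aa <- aa[-length(aa)]
      paste(aa, collapse = "")
    }, character(1))
    cds <- gsub("-", "", cds, fixed = TRUE)
  }
  cp <- back_translate_align(protein_alignment, cds, pairs, code)
  rows <- lapply(cp, function(p) {
    est <- kaks_estimate(ng86_counts(p$codons_a, p$codons_b, code))
    data.frame(id_a = p$id_a, id_b = p$id_b,
               S = est$S, N = est$N, Sd = est$Sd, Nd = est$Nd,
               Ka = est$Ka, Ks = est$Ks, ratio = est$ratio,
               selection = classify_selection(est$ratio, epsilon),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
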