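# Tandem / segmental duplication classification from a gene position
# table: rank-based tandem rule, anchor chaining into collinear blocks
# with a maximum intra-block gap, and mechanism assignment with tandem
# precedence.

check_gene_map <- function(loci) {
  need <- c("id", "chrom", "start", "end", "rank")
  miss <- setdiff(need, names(loci))
  if (length(miss))
    stop("gene map lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(loci$id)) stop("gene ids must be unique", call. = FALSE)
  if (any(loci$start > loci$end)) stop("start must be <= end", call. = FALSE)
  bad <- stats::aggregate(rank ~ chrom, loci, anyDuplicated)
  if (any(bad$rank > 0))
    stop("gene ranks must be unique within a chromosome", call. = FALSE)
  loci
}

locus_of <- function(loci, id) {
  k <- match(id, loci$id)
  if (is.na(k)) stop("gene ", id, " not in the gene map", call. = FALSE)
  loci[k, ]
}

#' Tandem-duplication test for a gene pair
#'
#' Two genes are tandem duplicates when they lie on the same chromosome
#' with at most `max_intervening` gene models between them (ranks, not bp).
#'
#' @param loci Gene map data frame with columns `id`, `chrom`, `start`,
#'   `end`, `rank` (rank = ordinal position of the gene model on its
#'   chromosome).
#' @param id_a,id_b Gene ids.
#' @param max_intervening Maximum intervening gene-model count (default 20).
#' @return List with `tandem` (logical) and `intervening` (count; `NA`
#'   when the genes are on different chromosomes).
#' @export
detect_tandem <- function(loci, id_a, id_b, max_intervening = 20L) {
  loci <- check_gene_map(loci)
  a <- locus_of(loci, id_a)
  b <- locus_of(loci, id_b)
  if (a$chrom != b$chrom)
    return(list(tandem = FALSE, intervening = NA_integer_))
  intervening <- abs(a$rank - b$rank) - 1L
  list(tandem = intervening <= max_intervening, intervening = intervening)
}

#' Chain anchor gene pairs into collinear blocks
#'
#' Chains putative homologous gene pairs (anchors) that preserve gene
#' order on both chromosomes, allowing at most `max_gap` base pairs
#' between consecutive anchors on each chromosome; maximal chains with at
#' least `min_anchors` anchors are emitted as collinear (syntenic) blocks.
#' Inverted blocks (order reversed on the second chromosome) are allowed.
#'
#' @param anchors Data frame with columns `id_a`, `chrom_a`, `start_a`,
#'   `end_a`, `id_b`, `chrom_b`, `start_b`, `end_b`.
#' @param max_gap Maximum bp between consecutive anchors on either
#'   chromosome (default 100000, i.e. 100 kb).
#' @param min_anchors Minimum anchors per emitted block (default 5).
#' @return Data frame of block spans (`block_id`, `chrom_a`, `start_a`,
#'   `end_a`, `chrom_b`, `start_b`, `end_b`, `n_anchors`) with the member
#'   anchors in attribute `"anchors"` (a data frame adding `block_id`).
#' @export
find_collinear_blocks <- function(anchors, max_gap = 100000, min_anchors = 5L) {
  empty <- data.frame(block_id = character(), chrom_a = character(),
                      start_a = numeric(), end_a = numeric(),
                      chrom_b = character(), start_b = numeric(),
                      end_b = numeric(), n_anchors = integer(),
                      stringsAsFactors = FALSE)
  attr(empty, "anchors") <- NULL
  if (is.null(anchors) || nrow(anchors) == 0L) return(empty)

  blocks <- list(); members <- list()
  for (cp in split(anchors, paste(anchors$chrom_a, anchors$chrom_b))) {
    cp <- cp[order(cp$start_a), ]
    chain <- 1L
    dir_b <- 0L
    for (k in seq_len(nrow(cp))[-1]) {
      prev <- cp[k - 1L, ]; cur <- cp[k, ]
      gap_a <- cur$start_a - prev$end_a
      this_dir <- sign(cur$start_b - prev$start_b)
      gap_b <- if (this_dir >= 0) cur$start_b - prev$end_b
               else prev$start_b - cur$end_b
      ok <- gap_a <= max_gap && gap_b <= max_gap &&
        (dir_b == 0L || this_dir == 0L || this_dir == dir_b)
      if (ok) {
        chain <- c(chain, k)
        if (dir_b == 0L) dir_b <- this_dir
      } else {
        if (length(chain) >= min_anchors)
          { blocks[[length(blocks) + 1L]] <- cp[chain, ] }
        chain <- k; dir_b <- 0L
      }
    }
    if (length(chain) >= min_anchors)
      blocks[[length(blocks) + 1L]] <- cp[chain, ]
  }
  if (!length(blocks)) return(empty)
  spans <- do.call(rbind, lapply(seq_along(blocks), function(i) {
    b <- blocks[[i]]
    data.frame(block_id = paste0("block", i),
               chrom_a = b$chrom_a[1], start_a = min(b$start_a),
               end_a = max(b$end_a),
               chrom_b = b$chrom_b[1], start_b = min(b$start_b),
               end_b = max(b$end_b),
               n_anchors = nrow(b), stringsAsFactors = FALSE)
  }))
  members <- do.call(rbind, lapply(seq_along(blocks), function(i)
    cbind(block_id = paste0("block", i), blocks[[i]],
          stringsAsFactors = FALSE)))
  attr(spans, "anchors") <- members
  spans
}

in_span <- function(chrom, pos, span_chrom, span_start, span_end)
  chrom == span_chrom & pos >= span_start & pos <= span_end

#' Classify duplicate gene pairs as tandem, segmental or unclassified
#'
#' Applies the tandem rule first (tandem takes precedence: proximal
#' duplicates inside a duplicated segment are still reported as tandem);
#' otherwise a pair is segmental when it is an anchor of a collinear
#' block, or both members fall inside the two spans of some block.
#'
#' @param pairs Data frame with columns `id_a`, `id_b`.
#' @param loci Gene map (see [detect_tandem()]).
#' @param blocks Block span table from [find_collinear_blocks()] or an
#'   externally supplied data frame with the same span columns (e.g.
#'   precomputed duplicated segments); may be `NULL`.
#' @param max_intervening Tandem rule parameter (default 20).
#' @return Data frame with `id_a`, `id_b`, `mechanism`
#'   (`"tandem"`/`"segmental"`/`"unclassified"`) and `evidence`
#'   (intervening gene count or block id).
#' @export
classify_duplication <- function(pairs, loci, blocks = NULL,
                                 max_intervening = 20L) {
  loci <- check_gene_map(loci)
  anchor_tab <- if (!is.null(blocks)) attr(blocks, "anchors") else NULL
  out <- lapply(seq_len(nrow(pairs)), function(r) {
    a_id <- pairs$id_a[r]; b_id <- pairs$id_b[r]
    td <- detect_tandem(loci, a_id, b_id, max_intervening)
    if (isTRUE(td$tandem))
      return(data.frame(id_a = a_id, id_b = b_id, mechanism = "tandem",
                        evidence = paste0("intervening=", td$intervening),
                        stringsAsFactors = FALSE))
    mech <- "unclassified"; ev <- NA_character_
    if (!is.null(blocks) && nrow(blocks)) {
      a <- locus_of(loci, a_id); b <- locus_of(loci, b_id)
      if (!is.null(anchor_tab)) {
        hit <- (anchor_tab$id_a == a_id & anchor_tab$id_b == b_id) |
               (anchor_tab$id_a == b_id & anchor_tab$id_b == a_id)
        if (any(hit)) { mech <- "segmental"; ev <- anchor_tab$block_id[hit][1] }
      }
      if (mech == "unclassified") {
        for (k in seq_len(nrow(blocks))) {
          bl <- blocks[k, ]
          fwd <- in_span(a$chrom, a$start, bl$chrom_a, bl$start_a, bl$end_a) &&
                 in_span(b$chrom, b$start, bl$chrom_b, bl$start_b, bl$end_b)
          rev <- in_span(b$chrom, b$start, bl$chrom_a, bl$start_a, bl$end_a) &&
                 in_span(a$chrom, a$start, bl$chrom_b, bl$start_b, bl$end_b)
          if (fwd || rev) { mech <- "segmental"; ev <- bl$block_id; break }
        }
      }
    }
    data.frame(id_a = a_id, id_b = b_id, mechanism = mech, evidence = ev,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
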