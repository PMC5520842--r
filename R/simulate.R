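# Seeded generators for every input the pipeline consumes: codon pairs
# diverged at a target Ks and Ka/Ks, chromosome gene maps with planted
# tandem arrays and duplicated segments, and MPSS-like tag-count matrices
# with planted fold responses. Truth records accompany every output so
# downstream calls can be scored without re-derivation.

STOP_CODONS <- c("TAA", "TAG", "TGA")

all_codons <- function() {
  g <- expand.grid(p3 = BASES, p2 = BASES, p1 = BASES,
                   stringsAsFactors = FALSE)
  paste0(g$p1, g$p2, g$p3)
}

#' Simulate a codon-sequence pair diverged at a target Ks and omega
#'
#' Draws a stop-free ancestral codon sequence and evolves two copies by
#' sequential random single-base mutations: proposals creating stop codons
#' are rejected, synonymous changes are always accepted, and nonsynonymous
#' changes are accepted with relative probability `omega`, until the
#' realized synonymous substitution count reaches `target_Ks` times the
#' ancestral synonymous site count. Under Nei-Gojobori site definitions
#' this acceptance rule makes the expected Ka/Ks equal `omega`.
#'
#' @param n_codons Number of codons (>= 1).
#' @param target_Ks Target synonymous divergence between the two copies
#'   (substitutions per synonymous site; >= 0).
#' @param omega Relative acceptance probability of nonsynonymous changes
#'   (Ka/Ks truth; >= 0).
#' @param seed Integer seed; fixes the output bit-for-bit.
#' @param code Genetic code table.
#' @return List with `cds_a`, `cds_b` (nucleotide strings), and `truth`
#'   (list: realized `syn_subs`, `nonsyn_subs`, ancestral synonymous sites
#'   `S_anc`, and the configuration).
#' @export
simulate_codon_pair <- function(n_codons, target_Ks, omega, seed = NULL,
                                code = standard_genetic_code()) {
  stopifnot(n_codons >= 1, target_Ks >= 0, omega >= 0)
  if (!is.null(seed)) set.seed(seed)
  codons64 <- all_codons()
  aa64 <- unname(code[codons64])          # translation by codon index
  sense_idx <- which(aa64 != "*")
  anc <- sample(sense_idx, n_codons, replace = TRUE)
  syn_frac <- vapply(codons64, codon_syn_sites, numeric(1), code = code)
  S_anc <- sum(syn_frac[anc])
  target_syn <- round(target_Ks * S_anc)
  # integer codon index = 16 (b1-1) + 4 (b2-1) + b3; changing position p
  # by delta bases shifts the index by delta * 4^(3-p)
  base_at <- function(idx, pos) ((idx - 1L) %/% c(16L, 4L, 1L)[pos]) %% 4L
  seqs <- list(anc, anc)
  syn_done <- 0L
  subs <- c(syn = 0L, nonsyn = 0L)
  acc_syn <- min(1, 1 / max(1, omega))
  acc_non <- min(1, omega / max(1, omega))
  proposals <- 0L
  cap <- 1000 * (target_syn + 10)
  while (syn_done < target_syn) {
    proposals <- proposals + 1L
    if (proposals > cap)
      stop("target synonymous divergence unreachable (saturation)",
           call. = FALSE)
    lineage <- sample.int(2L, 1L)
    k <- sample.int(n_codons, 1L)
    idx <- seqs[[lineage]][k]
    pos <- sample.int(3L, 1L)
    old_b <- base_at(idx, pos)
    new_b <- (old_b + sample.int(3L, 1L)) %% 4L
    mut <- idx + (new_b - old_b) * c(16L, 4L, 1L)[pos]
    if (aa64[mut] == "*") next
    if (aa64[mut] == aa64[idx]) {
      if (stats::runif(1) <= acc_syn) {
        seqs[[lineage]][k] <- mut
        syn_done <- syn_done + 1L
        subs[["syn"]] <- subs[["syn"]] + 1L
      }
    } else if (stats::runif(1) <= acc_non) {
      seqs[[lineage]][k] <- mut
      subs[["nonsyn"]] <- subs[["nonsyn"]] + 1L
    }
  }
  list(cds_a = paste(codons64[seqs[[1]]], collapse = ""),
       cds_b = paste(codons64[seqs[[2]]], collapse = ""),
       truth = list(n_codons = n_codons, target_Ks = target_Ks,
                    omega = omega, S_anc = S_anc,
                    syn_subs = subs[["syn"]], nonsyn_subs = subs[["nonsyn"]]))
}

#' Simulate a chromosome gene map with planted duplications
#'
#' Lays out ranked, non-overlapping gene models on the requested
#' chromosomes at a regular spacing, then plants tandem duplicate pairs
#' (specified intervening gene counts) and duplicated collinear segments
#' (anchor pairs at a specified rank stride, giving controllable intra-
#' block gaps).
#'
#' @param n_genes Named integer vector: genes per chromosome, e.g.
#'   `c(chr1 = 60, chr2 = 60)`.
#' @param spacing Start-to-start distance between consecutive gene models
#'   in bp (default 20000).
#' @param gene_length Gene model length in bp (default 4000).
#' @param tandem Data frame planting tandem pairs: columns `chrom`,
#'   `rank_a`, `intervening`; the partner sits at
#'   `rank_a + intervening + 1`.
#' @param segments Data frame planting duplicated segments: columns
#'   `chrom_a`, `chrom_b`, `start_a`, `start_b` (first anchor ranks),
#'   `n_anchors`, and optional `stride` (rank step between anchors,
#'   default 1).
#' @return List with `map` (gene map data frame: `id`, `chrom`, `start`,
#'   `end`, `strand`, `rank`), `anchors` (anchor pair table for
#'   [find_collinear_blocks()]), and `truth` (planted `tandem_pairs` and
#'   `segmental_pairs`).
#' @export
simulate_gene_map <- function(n_genes, spacing = 20000, gene_length = 4000,
                              tandem = NULL, segments = NULL) {
  stopifnot(gene_length < spacing)
  if (!length(n_genes))
    return(list(map = data.frame(id = character(), chrom = character(),
                                 start = numeric(), end = numeric(),
                                 strand = character(), rank = integer(),
                                 stringsAsFactors = FALSE),
                anchors = NULL,
                truth = list(tandem_pairs = NULL, segmental_pairs = NULL)))
  map <- do.call(rbind, lapply(names(n_genes), function(ch) {
    rk <- seq_len(n_genes[[ch]])
    data.frame(id = sprintf("%s_g%03d", ch, rk), chrom = ch,
               start = (rk - 1) * spacing + 1,
               end = (rk - 1) * spacing + gene_length,
               strand = "+", rank = rk, stringsAsFactors = FALSE)
  }))
  gene_at <- function(ch, rk) {
    hit <- map$id[map$chrom == ch & map$rank == rk]
    if (!length(hit))
      stop("layout infeasible: no gene at rank ", rk, " on ", ch,
           call. = FALSE)
    hit
  }
  tandem_pairs <- NULL
  if (!is.null(tandem) && nrow(tandem)) {
    tandem_pairs <- do.call(rbind, lapply(seq_len(nrow(tandem)), function(r) {
      a <- gene_at(tandem$chrom[r], tandem$rank_a[r])
      b <- gene_at(tandem$chrom[r],
                   tandem$rank_a[r] + tandem$intervening[r] + 1L)
      data.frame(id_a = a, id_b = b, intervening = tandem$intervening[r],
                 stringsAsFactors = FALSE)
    }))
  }
  anchors <- NULL; segmental_pairs <- NULL
  if (!is.null(segments) && nrow(segments)) {
    if (is.null(segments$stride)) segments$stride <- 1L
    seg_rows <- lapply(seq_len(nrow(segments)), function(r) {
      s <- segments[r, ]
      ra <- s$start_a + (seq_len(s$n_anchors) - 1L) * s$stride
      rb <- s$start_b + (seq_len(s$n_anchors) - 1L) * s$stride
      ga <- vapply(ra, gene_at, character(1), ch = s$chrom_a)
      gb <- vapply(rb, gene_at, character(1), ch = s$chrom_b)
      la <- map[match(ga, map$id), ]; lb <- map[match(gb, map$id), ]
      data.frame(id_a = ga, chrom_a = la$chrom, start_a = la$start,
                 end_a = la$end, id_b = gb, chrom_b = lb$chrom,
                 start_b = lb$start, end_b = lb$end,
                 segment = r, stringsAsFactors = FALSE)
    })
    anchors <- do.call(rbind, seg_rows)
    segmental_pairs <- anchors[, c("id_a", "id_b", "segment")]
  }
  list(map = map, anchors = anchors,
       truth = list(tandem_pairs = tandem_pairs,
                    segmental_pairs = segmental_pairs))
}

#' Simulate an MPSS-like tag-count matrix with planted responses
#'
#' Per-gene baseline abundance (tpm) is drawn from a heavy-tailed
#' log-normal distribution; each contrast contributes a control and a
#' treatment library; planted genes have their treatment abundance
#' multiplied by the requested fold; tag counts are Poisson draws at the
#' library sequencing depth.
#'
#' @param n_genes Number of genes.
#' @param contrasts Data frame with columns `contrast` and `class`.
#' @param planted Data frame with columns `gene` (index or id), `contrast`,
#'   `fold` (> 0; >= 2 plants an up response, <= 0.5 a down response).
#' @param depth Library sequencing depth in tags (default 1e6).
#' @param baseline_meanlog,baseline_sdlog Log-normal baseline parameters
#'   (defaults log(30), 1).
#' @param n_tissues Number of tissue libraries (presence profiling);
#'   default 4.
#' @param absent Optional data frame `gene`, `tissue` planting zero
#'   abundance for a gene in a tissue library.
#' @param seed Integer seed.
#' @return List with `counts` (matrix; a final `background` row absorbs
#'   the rest of the transcriptome so each library totals about `depth`
#'   tags), `meta` (library metadata:
#'   `library`, `role`, `contrast`, `class`), `contrasts`, and `truth`
#'   (planted responses with expected direction).
#' @export
simulate_expression <- function(n_genes, contrasts, planted = NULL,
                                depth = 1e6, baseline_meanlog = log(30),
                                baseline_sdlog = 1, n_tissues = 4L,
                                absent = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  genes <- sprintf("g%03d", seq_len(n_genes))
  base_tpm <- stats::rlnorm(n_genes, baseline_meanlog, baseline_sdlog)
  libs <- character(); roles <- character()
  lib_contrast <- character(); lib_class <- character()
  tpm_cols <- list()
  for (t in seq_len(n_tissues)) {
    nm <- sprintf("tissue%02d", t)
    col <- base_tpm
    if (!is.null(absent) && nrow(absent)) {
      hit <- absent$tissue == t | absent$tissue == nm
      col[resolve_gene(absent$gene[hit], genes)] <- 0
    }
    tpm_cols[[nm]] <- col
    libs <- c(libs, nm); roles <- c(roles, "tissue")
    lib_contrast <- c(lib_contrast, NA); lib_class <- c(lib_class, "tissues")
  }
  truth <- NULL
  for (k in seq_len(nrow(contrasts))) {
    cn <- contrasts$contrast[k]
    ctrl <- paste0("C_", cn); trt <- paste0("T_", cn)
    ctrl_tpm <- base_tpm
    trt_tpm <- base_tpm
    if (!is.null(planted) && nrow(planted)) {
      hit <- which(planted$contrast == cn)
      for (h in hit) {
        gi <- resolve_gene(planted$gene[h], genes)
        trt_tpm[gi] <- trt_tpm[gi] * planted$fold[h]
        truth <- rbind(truth, data.frame(
          gene = genes[gi], contrast = cn, class = contrasts$class[k],
          fold = planted$fold[h],
          direction = if (planted$fold[h] >= 1) "up" else "down",
          stringsAsFactors = FALSE))
      }
    }
    tpm_cols[[ctrl]] <- ctrl_tpm
    tpm_cols[[trt]] <- trt_tpm
    libs <- c(libs, ctrl, trt); roles <- c(roles, "control", "treatment")
    lib_contrast <- c(lib_contrast, cn, cn)
    lib_class <- c(lib_class, contrasts$class[k], contrasts$class[k])
  }
  # a background row absorbs the rest of the transcriptome so library
  # totals come out near the requested depth and tpm is on the real scale
  tpm_cols <- lapply(tpm_cols, function(col)
    c(col, max(0, 1e6 - sum(col))))
  genes <- c(genes, "background")
  counts <- vapply(tpm_cols, function(col)
    stats::rpois(length(col), col / 1e6 * depth), numeric(n_genes + 1L))
  counts <- matrix(counts, nrow = n_genes + 1L,
                   dimnames = list(genes, names(tpm_cols)))
  meta <- data.frame(library = libs, role = roles, contrast = lib_contrast,
                     class = lib_class, stringsAsFactors = FALSE)
  list(counts = counts, meta = meta, contrasts = contrasts, truth = truth)
}

resolve_gene <- function(g, genes) {
  if (is.numeric(g)) as.integer(g) else match(g, genes)
}
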