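# Protein-level family screening: signature-motif scan, physicochemical
# parameters (MW, pI, hydropathy-based transmembrane count), and the
# combined membership filter.

AA_LETTERS <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I", "L",
                "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Average (isotope-weighted) residue masses in Da; adding one water mass
# gives the mass of the intact peptide.
AA_AVG_MASS <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
WATER_MASS <- 18.0153

# Kyte-Doolittle hydropathy scale.
KD_HYDROPATHY <- c(
  A = 1.8,  R = -4.5, N = -3.5, D = -3.5, C = 2.5,
  E = -3.5, Q = -3.5, G = -0.4, H = -3.2, I = 4.5,
  L = 3.8,  K = -3.9, M = 1.9,  F = 2.8,  P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

#' Bjellqvist pKa set used for isoelectric-point calculation
#'
#' Acid-dissociation constants as used by the ExPASy ProtParam tool:
#' side-chain pKa for the ionizable residues, N-terminal pKa varying with
#' the first residue, and C-terminal pKa varying with the last residue.
#'
#' @return A list with components `sidechain` (named numeric), `nterm`
#'   (named numeric, `default` plus residue-specific entries) and `cterm`
#'   (same layout).
#' @export
bjellqvist_pka <- function() {
  list(
    sidechain = c(C = 9.0, D = 4.05, E = 4.45, H = 5.98,
                  K = 10.0, R = 12.0, Y = 10.0),
    nterm = c(default = 7.5, A = 7.59, M = 7.0, S = 6.93,
              P = 8.36, T = 6.82, V = 7.44, E = 7.7),
    cterm = c(default = 3.55, D = 4.55, E = 4.75)
  )
}

check_protein_sequence <- function(sequence, what = "sequence") {
  if (length(sequence) != 1L || is.na(sequence) || !nzchar(sequence))
    stop(what, " must be a single non-empty string", call. = FALSE)
  bad <- setdiff(strsplit(sequence, "")[[1]], c(AA_LETTERS, "X"))
  if (length(bad))
    stop(what, " contains invalid residue letters: ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  invisible(sequence)
}

#' Scan a protein for a signature motif with 'x' wildcards
#'
#' Finds every (possibly overlapping) occurrence of a motif such as the
#' OPT-family signature `"SPYxEVRxxVxxxDDP"`, where lowercase `x` matches
#' any single residue and uppercase letters must match exactly.
#'
#' @param sequence Amino-acid string (standard 20 letters plus `X`).
#' @param pattern Motif string; uppercase amino-acid letters plus lowercase
#'   `x` wildcards.
#' @return A data frame with columns `start` (1-based match position) and
#'   `matched` (the matched substring), ordered by `start`; zero rows when
#'   there is no match.
#' @examples
#' scan_motif("MMSPYAEVRGGVQQQDDPKK", "SPYxEVRxxVxxxDDP")
#' @export
scan_motif <- function(sequence, pattern) {
  check_protein_sequence(sequence)
  if (length(pattern) != 1L || !nzchar(pattern))
    stop("pattern must be a single non-empty string", call. = FALSE)
  pat_chars <- strsplit(pattern, "")[[1]]
  bad <- setdiff(pat_chars, c(AA_LETTERS, "x"))
  if (length(bad))
    stop("pattern contains invalid characters: ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  # lookahead regex so overlapping occurrences are all reported
  rx <- paste0("(?=", paste(ifelse(pat_chars == "x", ".", pat_chars),
                            collapse = ""), ")")
  m <- gregexpr(rx, sequence, perl = TRUE)[[1]]
  if (m[1] == -1L)
    return(data.frame(start = integer(), matched = character(),
                      stringsAsFactors = FALSE))
  starts <- as.integer(m)
  k <- length(pat_chars)
  starts <- starts[starts + k - 1L <= nchar(sequence)]
  data.frame(start = starts,
             matched = substring(sequence, starts, starts + k - 1L),
             stringsAsFactors = FALSE)
}

#' Molecular weight, isoelectric point and transmembrane-segment count
#'
#' Computes the protein parameters used for family screening: average
#' molecular weight in kDa (sum of residue masses plus one water),
#' isoelectric point (pH at which the Bjellqvist-model net charge is zero,
#' found by bisection over pH 0-14), and a hydropathy-based count of
#' predicted transmembrane segments (maximal runs of Kyte-Doolittle windows
#' whose mean exceeds a threshold).
#'
#' `X` residues carry zero charge and contribute a configurable average
#' mass (default: the mean of the 20 standard residue masses), with a
#' warning.
#'
#' @param sequence Amino-acid string.
#' @param pka_table pKa set as returned by [bjellqvist_pka()]; injectable
#'   for cross-checks against other tools.
#' @param hydropathy_scale Named per-residue hydropathy values
#'   (default Kyte-Doolittle).
#' @param tm_window Window length for the hydropathy scan (default 19).
#' @param tm_threshold Window-mean hydropathy above which a window is
#'   counted as membrane-spanning (default 1.6).
#' @param x_mass Average mass assigned to `X` residues.
#' @return A list with components `length`, `mw` (kDa), `pi`, `tm_count`.
#' @examples
#' protein_params("GG")$mw  # 0.1321191 kDa
#' @export
protein_params <- function(sequence,
                           pka_table = bjellqvist_pka(),
                           hydropathy_scale = KD_HYDROPATHY,
                           tm_window = 19L,
                           tm_threshold = 1.6,
                           x_mass = mean(AA_AVG_MASS)) {
  check_protein_sequence(sequence)
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  if (any(chars == "X"))
    warning("sequence contains X residues: excluded from charge, ",
            "assigned average mass ", signif(x_mass, 6), " Da")

  masses <- ifelse(chars == "X", x_mass, AA_AVG_MASS[chars])
  mw_kda <- (sum(masses) + WATER_MASS) / 1000

  pi <- solve_pi(chars, pka_table)

  # hydropathy windows: X gets the scale's mean so it is roughly neutral
  hyd <- ifelse(chars == "X", mean(hydropathy_scale), hydropathy_scale[chars])
  tm_count <- count_tm_segments(hyd, tm_window, tm_threshold)

  list(length = n, mw = mw_kda, pi = pi, tm_count = tm_count)
}

net_charge <- function(chars, ph, pka) {
  sc <- pka$sidechain
  pick <- function(tab, res) if (res %in% names(tab)) tab[[res]] else tab[["default"]]
  pos_pka <- c(pick(pka$nterm, chars[1]),
               sc[["K"]] * rep(1, sum(chars == "K")),
               sc[["R"]] * rep(1, sum(chars == "R")),
               sc[["H"]] * rep(1, sum(chars == "H")))
  neg_pka <- c(pick(pka$cterm, chars[length(chars)]),
               sc[["D"]] * rep(1, sum(chars == "D")),
               sc[["E"]] * rep(1, sum(chars == "E")),
               sc[["C"]] * rep(1, sum(chars == "C")),
               sc[["Y"]] * rep(1, sum(chars == "Y")))
  sum(1 / (1 + 10^(ph - pos_pka))) - sum(1 / (1 + 10^(neg_pka - ph)))
}

solve_pi <- function(chars, pka, tol = 1e-6) {
  lo <- 0; hi <- 14
  # net charge is strictly decreasing in pH
  for (i in seq_len(100)) {
    mid <- (lo + hi) / 2
    if (net_charge(chars, mid, pka) > 0) lo <- mid else hi <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

count_tm_segments <- function(hyd, window, threshold) {
  n <- length(hyd)
  if (n < window) return(0L)
  means <- stats::filter(hyd, rep(1 / window, window), sides = 1)
  means <- means[window:n]              # mean of windows ending at window..n
  qual <- which(means > threshold)      # window start = index
  if (!length(qual)) return(0L)
  # merge windows that share residues (starts closer than `window`)
  breaks <- which(diff(qual) >= window)
  length(breaks) + 1L
}

#' Filter candidate proteins to family members
#'
#' Retains candidates that carry at least one signature-motif hit and whose
#' protein parameters fall inside the acceptance window, attaching the
#' computed parameters and motif hits to each survivor. Input order is
#' preserved.
#'
#' @param candidates Named character vector (or data frame with columns
#'   `id`, `sequence`) of candidate protein sequences.
#' @param pattern Signature motif, as for [scan_motif()].
#' @param params_window Optional list of acceptance ranges; recognised
#'   elements are `length`, `mw`, `tm_count`, each a `c(min, max)` pair
#'   (use `-Inf`/`Inf` for open ends).
#' @param ... Passed to [protein_params()].
#' @return A data frame with one row per retained member: `id`,
#'   `length_aa`, `mw_kda`, `pi`, `tm_count`, `motif_starts` (comma-joined
#'   positions), mirroring a family summary table.
#' @export
filter_family <- function(candidates, pattern, params_window = list(), ...) {
  if (is.data.frame(candidates)) {
    ids <- candidates$id
    seqs <- candidates$sequence
  } else {
    ids <- names(candidates)
    seqs <- unname(candidates)
  }
  if (is.null(ids) || anyDuplicated(ids))
    stop("candidate ids must be present and unique", call. = FALSE)

  in_range <- function(x, rng) {
    if (is.null(rng)) TRUE else x >= rng[1] && x <= rng[2]
  }
  rows <- lapply(seq_along(ids), function(i) {
    hits <- scan_motif(seqs[i], pattern)
    if (nrow(hits) == 0L) return(NULL)
    pp <- protein_params(seqs[i], ...)
    if (!in_range(pp$length, params_window$length) ||
        !in_range(pp$mw, params_window$mw) ||
        !in_range(pp$tm_count, params_window$tm_count)) return(NULL)
    data.frame(id = ids[i], length_aa = pp$length, mw_kda = pp$mw,
               pi = pp$pi, tm_count = pp$tm_count,
               motif_starts = paste(hits$start, collapse = ","),
               stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows))
    return(data.frame(id = character(), length_aa = integer(),
                      mw_kda = numeric(), pi = numeric(),
                      tm_count = integer(), motif_starts = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
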