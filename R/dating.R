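# Molecular-clock dating of duplication events (T = Ks / 2 lambda),
# evolutionary-stage binning with nearest-bin fallback and per-event
# overrides, ancestral-gene counting, and the combined event report.

#' Rice neutral substitution rate (substitutions per silent site per year)
#' @export
RICE_LAMBDA <- 6.5e-9

# truncate (not round) to 2 decimals; the small epsilon keeps exact decimal
# values from falling just below the boundary in binary floating point
trunc2 <- function(x) floor(x * 100 + 1e-9) / 100
trunc4 <- function(x) floor(x * 10000 + 1e-7) / 10000

#' Date a duplication event from synonymous divergence
#'
#' Molecular-clock conversion T = Ks / (2 lambda), returned in million
#' years. Reports derived from this value truncate (not round) to two
#' decimals.
#'
#' @param Ks Synonymous substitutions per synonymous site (>= 0).
#' @param lambda Substitutions per silent site per year (> 0); default the
#'   rice rate 6.5e-9.
#' @return Date in million years (full precision).
#' @examples
#' date_event(0.9061)  # 69.7 My
#' @export
date_event <- function(Ks, lambda = RICE_LAMBDA) {
  if (any(lambda <= 0)) stop("lambda must be positive", call. = FALSE)
  if (any(Ks < 0)) stop("Ks must be nonnegative", call. = FALSE)
  Ks / (2 * lambda) / 1e6
}

#' Default evolutionary-stage configuration
#'
#' Three stages in million years: stage 1 from the origin of the grasses
#' to the rice/maize divergence (70-50 My), stage 2 to the
#' Zizaniinae/Oryzinae separation (50-20 My), stage 3 to the branching of
#' Oryza from the remaining Oryzeae (20-9 My).
#'
#' @return List with `lambda` and `bins` (3x2 matrix of upper/lower
#'   boundaries in My, strictly decreasing).
#' @export
stage_config <- function() {
  list(lambda = RICE_LAMBDA,
       bins = matrix(c(70, 50, 50, 20, 20, 9), nrow = 3, byrow = TRUE,
                     dimnames = list(paste0("stage", 1:3), c("upper", "lower"))))
}

#' Assign a duplication date to an evolutionary stage
#'
#' Dates inside a bin (lower <= date <= upper; interior boundaries belong
#' to the older stage) are assigned to it; dates outside all bins get the
#' nearest bin with `out_of_range = TRUE`. A per-event override (stage
#' number) wins over binning and is never flagged.
#'
#' @param date_my Date in million years (>= 0).
#' @param config Stage configuration, see [stage_config()].
#' @param override Optional stage number (1-3) forcing the assignment.
#' @return List with `stage` (integer) and `out_of_range` (logical).
#' @export
assign_stage <- function(date_my, config = stage_config(), override = NULL) {
  stopifnot(date_my >= 0)
  if (!is.null(override) && !is.na(override)) {
    stopifnot(override %in% seq_len(nrow(config$bins)))
    return(list(stage = as.integer(override), out_of_range = FALSE))
  }
  bins <- config$bins
  for (s in seq_len(nrow(bins))) {
    if (date_my <= bins[s, "upper"] && date_my >= bins[s, "lower"])
      return(list(stage = s, out_of_range = FALSE))
  }
  # outside every bin: nearest bin by distance to its boundary
  dist <- pmin(abs(date_my - bins[, "upper"]), abs(date_my - bins[, "lower"]))
  list(stage = unname(which.min(dist)), out_of_range = TRUE)
}

#' Number of ancestral genes implied by a set of duplication events
#'
#' Builds a graph with the duplicated pairs as edges over the family
#' members; each connected component of duplicates descends from one
#' ancestral gene, so the ancestral count is the total member count minus
#' the number of duplication-derived genes (vertices minus components).
#'
#' @param members Character vector of family gene ids.
#' @param events Data frame with columns `id_a`, `id_b` (duplicated
#'   pairs); every id must be a member.
#' @return Integer count of ancestral genes.
#' @examples
#' ancestral_count(letters[1:3], data.frame(id_a = "a", id_b = "b"))  # 2
#' @export
ancestral_count <- function(members, events) {
  if (is.null(events) || nrow(events) == 0L) return(length(members))
  ids <- unique(c(events$id_a, events$id_b))
  bad <- setdiff(ids, members)
  if (length(bad))
    stop("event genes not in members: ", paste(bad, collapse = ", "),
         call. = FALSE)
  g <- igraph::graph_from_data_frame(
    unique(events[, c("id_a", "id_b")]), directed = FALSE)
  comp <- igraph::components(g)
  as.integer(length(members) - (igraph::vcount(g) - comp$no))
}

#' Assemble the per-pair duplication event report
#'
#' Joins Ka/Ks estimates, duplication mechanisms, clock dates and stage
#' assignments into one record per duplicated pair: Ka, Ks, Ka/Ks ratio
#' (truncated to 4 decimals for display), date in My (truncated to 2
#' decimals), mechanism, selection regime and purifying yes/no call,
#' ordered by date descending.
#'
#' @param kaks Data frame with `id_a`, `id_b`, `Ka`, `Ks` (e.g. from
#'   [kaks_pairs()] or a printed-values fixture).
#' @param mechanisms Data frame with `id_a`, `id_b`, `mechanism` (e.g.
#'   from [classify_duplication()]).
#' @param config Stage configuration, see [stage_config()].
#' @param overrides Optional data frame `id_a`, `id_b`, `stage` of manual
#'   stage assignments.
#' @param epsilon Neutral band for [classify_selection()].
#' @return Data frame with columns `pair`, `Ka`, `Ks`, `ratio`,
#'   `date_my`, `mechanism`, `selection`, `purifying`, `stage`,
#'   `out_of_range`.
#' @export
build_event_report <- function(kaks, mechanisms, config = stage_config(),
                               overrides = NULL, epsilon = 0) {
  if (is.null(kaks) || nrow(kaks) == 0L)
    return(data.frame(pair = character(), Ka = numeric(), Ks = numeric(),
                      ratio = numeric(), date_my = numeric(),
                      mechanism = character(), selection = character(),
                      purifying = character(), stage = integer(),
                      out_of_range = logical(), stringsAsFactors = FALSE))
  pair_key <- function(d) paste(d$id_a, d$id_b, sep = "/")
  rev_key <- function(d) paste(d$id_b, d$id_a, sep = "/")
  mech_for <- function(key) {
    hit <- which(pair_key(mechanisms) == key | rev_key(mechanisms) == key)
    if (!length(hit)) stop("no mechanism for pair ", key, call. = FALSE)
    mechanisms$mechanism[hit[1]]
  }
  override_for <- function(key) {
    if (is.null(overrides)) return(NULL)
    hit <- which(pair_key(overrides) == key | rev_key(overrides) == key)
    if (!length(hit)) NULL else overrides$stage[hit[1]]
  }
  rows <- lapply(seq_len(nrow(kaks)), function(r) {
    key <- pair_key(kaks[r, ])
    Ka <- kaks$Ka[r]; Ks <- kaks$Ks[r]
    ratio <- if (Ks > 0) Ka / Ks else NA_real_
    date <- date_event(Ks, config$lambda)
    st <- assign_stage(date, config, override_for(key))
    sel <- classify_selection(ratio, epsilon)
    data.frame(pair = key, Ka = Ka, Ks = Ks, ratio = trunc4(ratio),
               date_my = trunc2(date), mechanism = mech_for(key),
               selection = sel,
               purifying = if (sel == "purifying") "Yes" else "No",
               stage = st$stage, out_of_range = st$out_of_range,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out[order(-out$date_my), , drop = FALSE]
}
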