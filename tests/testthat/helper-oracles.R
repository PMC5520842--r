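# Independent oracles used across the suite. These are deliberately
# written from first principles (naive scans, exhaustive enumeration,
# graph traversal) and never call the package internals they check.

AA20 <- strsplit("ARNDCEQGHILKMFPSTWYV", "")[[1]]
NT4 <- c("A", "C", "G", "T")

random_protein <- function(n) paste(sample(AA20, n, replace = TRUE),
                                    collapse = "")

# all-offsets motif scan: position-by-position comparison
naive_motif_scan <- function(sequence, pattern) {
  s <- strsplit(sequence, "")[[1]]
  p <- strsplit(pattern, "")[[1]]
  k <- length(p)
  hits <- integer()
  if (length(s) >= k) {
    for (i in seq_len(length(s) - k + 1L)) {
      ok <- TRUE
      for (j in seq_len(k)) {
        if (p[j] != "x" && p[j] != s[i + j - 1L]) { ok <- FALSE; break }
      }
      if (ok) hits <- c(hits, i)
    }
  }
  hits
}

# --- NG86 oracle: direct enumeration, no memoization, no shared code ----

GC <- Biostrings::GENETIC_CODE

oracle_syn_sites <- function(codon) {
  aa <- GC[[codon]]
  total <- 0
  for (pos in 1:3) {
    ch <- strsplit(codon, "")[[1]]
    syn <- 0; viable <- 0
    for (b in NT4) {
      if (b == ch[pos]) next
      mut <- ch; mut[pos] <- b
      maa <- GC[[paste(mut, collapse = "")]]
      if (maa == "*") next
      viable <- viable + 1
      if (maa == aa) syn <- syn + 1
    }
    if (viable > 0) total <- total + syn / viable
  }
  total
}

perms_of <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in perms_of(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], rest)
  out
}

# (S, N, Sd, Nd) for a single aligned codon pair by brute enumeration
oracle_ng86_codon <- function(c1, c2) {
  S <- (oracle_syn_sites(c1) + oracle_syn_sites(c2)) / 2
  a <- strsplit(c1, "")[[1]]; b <- strsplit(c2, "")[[1]]
  dpos <- which(a != b)
  if (!length(dpos)) return(c(S = S, N = 3 - S, Sd = 0, Nd = 0))
  paths <- list()
  for (ord in perms_of(dpos)) {
    cur <- a; sd <- 0; nd <- 0; blocked <- FALSE
    for (pos in ord) {
      before <- GC[[paste(cur, collapse = "")]]
      cur[pos] <- b[pos]
      after_codon <- paste(cur, collapse = "")
      after <- GC[[after_codon]]
      if (after == "*" && !identical(cur, b)) blocked <- TRUE
      if (after == before) sd <- sd + 1 else nd <- nd + 1
    }
    paths[[length(paths) + 1L]] <- list(sd = sd, nd = nd, blocked = blocked)
  }
  ok <- Filter(function(p) !p$blocked, paths)
  if (!length(ok)) ok <- paths
  c(S = S, N = 3 - S,
    Sd = mean(vapply(ok, `[[`, numeric(1), "sd")),
    Nd = mean(vapply(ok, `[[`, numeric(1), "nd")))
}

sense_codons <- function() {
  g <- expand.grid(NT4, NT4, NT4, stringsAsFactors = FALSE)
  all <- paste0(g[[3]], g[[2]], g[[1]])
  all[GC[all] != "*"]
}

# random sense codon at most `max_diff` base changes away from `codon`
random_mutant <- function(codon, max_diff = 2) {
  repeat {
    ch <- strsplit(codon, "")[[1]]
    nd <- sample.int(max_diff + 1L, 1L) - 1L
    if (nd > 0) {
      for (pos in sample(1:3, nd)) ch[pos] <- sample(setdiff(NT4, ch[pos]), 1)
    }
    out <- paste(ch, collapse = "")
    if (GC[[out]] != "*") return(out)
  }
}

# random sense-codon pair with at most `max_diff` differing positions,
# both endpoints sense codons
random_codon_pair <- function(max_diff = 2) {
  repeat {
    c1 <- sample(sense_codons(), 1)
    nd <- sample.int(max_diff + 1L, 1L) - 1L
    ch <- strsplit(c1, "")[[1]]
    if (nd > 0) {
      for (pos in sample(1:3, nd)) ch[pos] <- sample(setdiff(NT4, ch[pos]), 1)
    }
    c2 <- paste(ch, collapse = "")
    if (GC[[c2]] != "*") return(c(c1, c2))
  }
}

# --- tree oracles: random additive trees, path metrics, topologies ------

# random unrooted binary tree over `taxa`; edges: data.frame(a, b, len);
# internal nodes are "i1", "i2", ...
random_unrooted_tree <- function(taxa, min_len = 0.05, max_len = 1) {
  stopifnot(length(taxa) >= 3)
  n_int <- 1L
  edges <- data.frame(a = "i1", b = taxa[1:3],
                      len = stats::runif(3, min_len, max_len),
                      stringsAsFactors = FALSE)
  for (tx in taxa[-(1:3)]) {
    e <- sample.int(nrow(edges), 1L)
    n_int <- n_int + 1L
    mid <- paste0("i", n_int)
    old <- edges[e, ]
    cut <- stats::runif(1, 0.2, 0.8) * old$len
    edges <- edges[-e, ]
    edges <- rbind(edges,
      data.frame(a = old$a, b = mid, len = cut, stringsAsFactors = FALSE),
      data.frame(a = mid, b = old$b, len = old$len - cut,
                 stringsAsFactors = FALSE),
      data.frame(a = mid, b = tx, len = stats::runif(1, min_len, max_len),
                 stringsAsFactors = FALSE))
  }
  edges
}

# leaf-to-leaf path-length matrix by breadth-first traversal
edge_tree_distances <- function(edges, taxa) {
  nodes <- unique(c(edges$a, edges$b))
  adj <- lapply(stats::setNames(vector("list", length(nodes)), nodes),
                function(x) NULL)
  for (k in seq_len(nrow(edges))) {
    adj[[edges$a[k]]] <- rbind(adj[[edges$a[k]]],
                               data.frame(to = edges$b[k], len = edges$len[k]))
    adj[[edges$b[k]]] <- rbind(adj[[edges$b[k]]],
                               data.frame(to = edges$a[k], len = edges$len[k]))
  }
  d <- matrix(0, length(taxa), length(taxa), dimnames = list(taxa, taxa))
  for (src in taxa) {
    dist <- stats::setNames(rep(NA_real_, length(nodes)), nodes)
    dist[src] <- 0
    queue <- src
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      nb <- adj[[cur]]
      for (k in seq_len(NROW(nb))) {
        if (is.na(dist[nb$to[k]])) {
          dist[nb$to[k]] <- dist[cur] + nb$len[k]
          queue <- c(queue, nb$to[k])
        }
      }
    }
    d[src, taxa] <- dist[taxa]
  }
  d
}

# canonical split set of an edge tree (sides not containing the first
# sorted taxon; trivial splits dropped) — mirrors the package's canonical
# form but computed by component labeling, not via ape
edge_tree_splits <- function(edges, taxa) {
  anchor <- sort(taxa)[1]
  out <- character()
  for (k in seq_len(nrow(edges))) {
    rest <- edges[-k, ]
    # component containing edges$b[k]
    comp <- edges$b[k]
    repeat {
      grow <- unique(c(rest$a[rest$b %in% comp], rest$b[rest$a %in% comp]))
      grow <- setdiff(grow, comp)
      if (!length(grow)) break
      comp <- c(comp, grow)
    }
    side <- intersect(comp, taxa)
    if (anchor %in% side) side <- setdiff(taxa, side)
    if (length(side) >= 2 && length(side) <= length(taxa) - 2)
      out <- c(out, paste(sort(side), collapse = "|"))
  }
  unique(out)
}

# all unrooted binary topologies over `taxa` (unit branch lengths)
enumerate_topologies <- function(taxa) {
  base <- data.frame(a = "i1", b = taxa[1:3], len = 1,
                     stringsAsFactors = FALSE)
  trees <- list(base)
  n_int <- 1L
  for (tx in taxa[-(1:3)]) {
    n_int <- n_int + 1L
    mid <- paste0("i", n_int)
    nxt <- list()
    for (tr in trees) {
      for (e in seq_len(nrow(tr))) {
        old <- tr[e, ]
        nt <- rbind(tr[-e, ],
          data.frame(a = old$a, b = mid, len = 1, stringsAsFactors = FALSE),
          data.frame(a = mid, b = old$b, len = 1, stringsAsFactors = FALSE),
          data.frame(a = mid, b = tx, len = 1, stringsAsFactors = FALSE))
        nxt[[length(nxt) + 1L]] <- nt
      }
    }
    trees <- nxt
  }
  trees
}

# least-squares branch lengths of `dm` on a fixed topology; returns the
# residual sum of squares (0 iff dm is additive on that topology)
topology_rss <- function(edges, dm) {
  taxa <- rownames(dm)
  pairs <- utils::combn(taxa, 2)
  # incidence: which edges lie on the path between each leaf pair
  nodes <- unique(c(edges$a, edges$b))
  X <- matrix(0, ncol(pairs), nrow(edges))
  y <- numeric(ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    src <- pairs[1, p]; dst <- pairs[2, p]
    # path by DFS remembering the edge sequence
    path <- find_path(edges, src, dst)
    X[p, path] <- 1
    y[p] <- dm[src, dst]
  }
  fit <- stats::lm.fit(X, y)
  sum(fit$residuals^2)
}

find_path <- function(edges, src, dst) {
  # DFS from src to dst; returns indices of edges on the path
  stack <- list(list(node = src, used = integer()))
  visited <- character()
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    if (top$node == dst) return(top$used)
    if (top$node %in% visited) next
    visited <- c(visited, top$node)
    inc <- which(edges$a == top$node | edges$b == top$node)
    for (k in inc) {
      other <- if (edges$a[k] == top$node) edges$b[k] else edges$a[k]
      if (!other %in% visited)
        stack[[length(stack) + 1L]] <- list(node = other,
                                            used = c(top$used, k))
    }
  }
  stop("no path found")
}

# clean two-clade alignment: within-group identity columns plus taxon-
# specific variable columns; the AB split is supported by every informative
# column
two_clade_alignment <- function(groupA, groupB, n_info = 30, n_var = 6) {
  taxa <- c(groupA, groupB)
  rows <- stats::setNames(rep("", length(taxa)), taxa)
  for (k in seq_len(n_info)) {
    for (t in groupA) rows[t] <- paste0(rows[t], "A")
    for (t in groupB) rows[t] <- paste0(rows[t], "R")
  }
  # distinguish taxa within groups with private substitutions
  for (i in seq_along(taxa)) {
    for (k in seq_len(n_var)) {
      block <- rep("G", length(taxa))
      if (k <= i) block[i] <- "W"
      rows <- paste0(rows, block)
      names(rows) <- taxa
    }
  }
  # constant padding so p stays well below 1
  stats::setNames(paste0(rows, strrep("L", 40)), taxa)
}
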