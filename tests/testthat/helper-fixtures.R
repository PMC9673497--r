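# Shared fixtures, built in code. Heavy objects (the default benchmark and
# the pipeline run on it) are generated once per session and cached.

.fixture_env <- new.env(parent = emptyenv())

# a random valid CDS (ATG ... sense codons ... stop)
random_cds <- function(n_codons = 20L) {
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  paste0("ATG", paste(sample(sense, n_codons, replace = TRUE),
                      collapse = ""),
         sample(c("TAA", "TAG", "TGA"), 1L))
}

random_protein <- function(n = 30L) {
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  paste(sample(aa, n, replace = TRUE), collapse = "")
}

# translate an SLNP / SLAAP into the equivalent regular expression (the
# independent matcher oracle)
slnp_regex <- function(pattern) {
  masks <- slnp_parse(pattern)
  bases <- c("A", "C", "G", "T")
  paste(vapply(masks, function(m) {
    b <- bases[bitwAnd(m, c(1L, 2L, 4L, 8L)) > 0L]
    if (length(b) == 4L) "[ACGT]" else if (length(b) == 1L) b
    else paste0("[", paste(b, collapse = ""), "]")
  }, character(1)), collapse = "")
}

slaap_regex <- function(pattern) {
  std <- "[ARNDCQEGHILKMFPSTWYV]"
  paste(vapply(strsplit(pattern, "")[[1L]], function(ch)
    if (ch == "x") std else ch, character(1)), collapse = "")
}

# default-config benchmark + full pipeline run, shared across test files
shared_benchmark <- function() {
  if (is.null(.fixture_env$bench)) {
    dir <- file.path(tempdir(), "isgfinder-bench")
    .fixture_env$bench <- list(
      dir = dir,
      out = make_benchmark(dir, benchmark_config(seed = 42L)))
  }
  .fixture_env$bench
}

shared_pipeline <- function() {
  if (is.null(.fixture_env$pipe)) {
    bm <- shared_benchmark()
    .fixture_env$pipe <- run_isg_pipeline(bm$dir, seed = 11L)
  }
  .fixture_env$pipe
}

# small graph helpers for the network oracle
random_er_graph <- function(n, p_edge) {
  pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  keep <- stats::runif(nrow(pairs)) < p_edge
  data.frame(id_a = paste0("v", pairs[keep, 1]),
             id_b = paste0("v", pairs[keep, 2]),
             confidence = 0.9)
}

# brute-force recomputation of the eight node metrics (independent of the
# package implementation: BFS + explicit shortest-path counting)
brute_metrics <- function(edges) {
  nodes <- sort(unique(c(edges$id_a, edges$id_b)))
  n <- length(nodes)
  A <- matrix(0L, n, n, dimnames = list(nodes, nodes))
  for (r in seq_len(nrow(edges))) {
    i <- match(edges$id_a[r], nodes)
    j <- match(edges$id_b[r], nodes)
    A[i, j] <- A[j, i] <- 1L
  }
  D <- matrix(Inf, n, n)
  S <- matrix(0, n, n) # shortest-path counts
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    sig <- rep(0, n)
    dist[s] <- 0
    sig[s] <- 1
    frontier <- s
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) {
        for (w in which(A[v, ] == 1L)) {
          if (!is.finite(dist[w])) {
            dist[w] <- dist[v] + 1
            nxt <- c(nxt, w)
          }
          if (dist[w] == dist[v] + 1) sig[w] <- sig[w] + sig[v]
        }
      }
      frontier <- unique(nxt)
    }
    D[s, ] <- dist
    S[s, ] <- sig
  }
  deg <- rowSums(A)
  out <- data.frame(matrix(0, n, 8))
  names(out) <- c("avg_shortest_path", "closeness", "betweenness", "stress",
                  "degree", "neighbourhood_connectivity",
                  "clustering_coefficient", "topological_coefficient")
  rownames(out) <- nodes
  for (v in seq_len(n)) {
    reach <- is.finite(D[v, ]) & seq_len(n) != v
    asp <- if (any(reach)) mean(D[v, reach]) else 0
    # path counting through v
    Dsv <- matrix(D[, v], n, n)
    Dvt <- matrix(D[v, ], n, n, byrow = TRUE)
    on_path <- is.finite(D) & (Dsv + Dvt == D)
    contrib <- outer(S[, v], S[v, ]) * on_path
    frac <- ifelse(on_path & S > 0, contrib / S, 0)
    mask <- row(D) != v & col(D) != v & row(D) != col(D)
    stress_v <- sum(contrib[mask]) / 2
    btw_v <- sum(frac[mask]) / 2 / (if (n > 2) (n - 1) * (n - 2) / 2 else 1)
    nb <- which(A[v, ] == 1L)
    nc <- if (length(nb)) mean(deg[nb]) else 0
    cc <- if (deg[v] >= 2) {
      e <- sum(A[nb, nb]) / 2
      2 * e / (deg[v] * (deg[v] - 1))
    } else 0
    tc <- if (deg[v] >= 2) {
      shared <- A[v, , drop = TRUE] %*% A # row: shared-neighbour counts
      js <- numeric(0)
      for (m in seq_len(n)) {
        if (m == v || shared[m] == 0) next
        js <- c(js, shared[m] + A[v, m])
      }
      if (length(js)) mean(js / deg[v]) else 0
    } else 0
    out[v, ] <- c(asp, if (asp > 0) 1 / asp else 0, btw_v, stress_v,
                  deg[v], nc, cc, tc)
  }
  out
}
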