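# Independent oracles and shared fixtures for the test suite.
# Oracles are deliberately written against plain data structures (no reuse of
# the package's graph/geometry code paths).

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, fn) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, fn(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

fx_library_dir <- function() {
  cached("lib_dir", function() {
    d <- file.path(tempdir(), "residuekit-fixtures")
    mini_component_library(d, gzip = TRUE)
    d
  })
}

fx_library <- function() {
  cached("lib", function() {
    suppressMessages(read_component_library(
      file.path(fx_library_dir(), "mini_components.sdf")
    ))
  })
}

fx_decoy_library <- function() {
  cached("decoys", function() {
    suppressMessages(read_component_library(
      decoy_component_library(file.path(tempdir(), "residuekit-decoys"))
    ))
  })
}

fx_defn_gly <- function() cached("defn_gly", function() build_residue("NCC(=O)O"))
fx_defn_ala <- function() cached("defn_ala", function() build_residue("N[C@@H](C)C(=O)O"))
fx_defn_thr <- function() {
  cached("defn_thr", function() build_residue("N[C@@H]([C@H](O)C)C(=O)O"))
}

# plain-R breadth-first search over an edge list; returns the minimum number
# of bonds between two atoms, Inf when disconnected
oracle_bfs_bonds <- function(edges, from, to) {
  if (from == to) return(0)
  adj <- split(c(edges[, 2], edges[, 1]), c(edges[, 1], edges[, 2]))
  dist <- c()
  dist[as.character(from)] <- 0
  queue <- from
  while (length(queue) > 0) {
    v <- queue[1]
    queue <- queue[-1]
    for (w in adj[[as.character(v)]]) {
      if (is.null(dist[as.character(w)]) || is.na(dist[as.character(w)])) {
        dist[as.character(w)] <- dist[as.character(v)] + 1
        if (w == to) return(dist[as.character(w)])
        queue <- c(queue, w)
      }
    }
  }
  Inf
}

# classification oracle: all-pairs BFS over heavy-atom bonds between the
# production-detected sites (the path search itself is what is being checked)
oracle_classify <- function(mol) {
  mol <- residuekit::parse_molecule(mol)
  carb <- find_carboxyl_sites(mol)
  amin <- find_amine_sites(mol)
  if (nrow(carb) == 0 || nrow(amin) == 0) return("rejected")
  heavy <- mol$atoms$idx[mol$atoms$heavy]
  b <- mol$bonds[mol$bonds$a1 %in% heavy & mol$bonds$a2 %in% heavy, ]
  edges <- cbind(b$a1, b$a2)
  best <- Inf
  for (n in amin$nitrogen_index) {
    for (cc in carb$carbon_index) {
      best <- min(best, oracle_bfs_bonds(edges, n, cc))
    }
  }
  if (!is.finite(best) || best >= 5) "rejected"
  else c("alpha", "beta", "gamma")[best - 1]
}

# substructure-count oracle via the independent Open Babel SMARTS engine
oracle_smarts_count <- function(smiles, pattern) {
  n <- ChemmineOB::forEachMol("SMILES", smiles, function(m) {
    ChemmineOB::smartsSearch_OB(c(m), pattern)
  })
  as.integer(n[[1]])
}

# independent banding rule, written directly from the printed inequalities
oracle_omega_band <- function(x) {
  x <- abs(x)
  if (any(is.na(x))) return("bad")
  if (any(x > 30 & x < 120)) return("bad")
  if (any(x >= 120 & x < 150)) return("borderline")
  "good"
}

# random rigid motion applied to a coordinate_set
rigid_motion <- function(cs, seed = 1) {
  set.seed(seed)
  th <- stats::runif(3, 0, 2 * pi)
  rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])),
              c(0, sin(th[1]), cos(th[1])))
  ry <- rbind(c(cos(th[2]), 0, sin(th[2])), c(0, 1, 0),
              c(-sin(th[2]), 0, cos(th[2])))
  rz <- rbind(c(cos(th[3]), -sin(th[3]), 0),
              c(sin(th[3]), cos(th[3]), 0), c(0, 0, 1))
  R <- rx %*% ry %*% rz
  t0 <- stats::runif(3, -5, 5)
  a <- cs$atoms
  m <- as.matrix(a[, c("x", "y", "z")]) %*% t(R)
  a$x <- m[, 1] + t0[1]
  a$y <- m[, 2] + t0[2]
  a$z <- m[, 3] + t0[3]
  coordinate_set(a)
}

write_text <- function(lines, path) {
  writeLines(lines, path)
  path
}
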