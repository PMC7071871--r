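# Independent reference implementations used as oracles. These deliberately
# share no code with the package internals: the persistence oracle is a plain
# dense GF(2) boundary-matrix reduction over all simplices, the component
# oracle is an R union-find, and the clustering oracle cuts the minimum
# spanning tree from vegan.

# full-filtration Vietoris-Rips persistence (dims 0 and 1) by textbook
# column reduction; distance scale; feasible for n <= ~15
oracle_rips_pairs <- function(D, cap = Inf) {
  n <- nrow(D)
  vals <- rep(0, n)
  dims <- rep(0L, n)
  faces <- vector("list", n)
  idx_edge <- matrix(NA_integer_, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (D[i, j] <= cap) {
        vals <- c(vals, D[i, j]); dims <- c(dims, 1L)
        faces <- c(faces, list(c(i, j)))
        idx_edge[i, j] <- length(vals)
      }
    }
  }
  if (n >= 3) {
    for (i in seq_len(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
      w <- max(D[i, j], D[i, k], D[j, k])
      if (w <= cap) {
        vals <- c(vals, w); dims <- c(dims, 2L)
        faces <- c(faces, list(c(idx_edge[i, j], idx_edge[i, k], idx_edge[j, k])))
      }
    }
  }
  ord <- order(vals, dims, seq_along(vals))  # faces precede cofaces
  pos <- integer(length(ord)); pos[ord] <- seq_along(ord)
  cols <- lapply(ord, function(s) sort(pos[faces[[s]]]))
  low_of <- integer(length(cols))  # 0 = empty column
  owner <- integer(length(cols))
  pairs <- list()
  for (j in seq_along(cols)) {
    col <- cols[[j]]
    while (length(col) > 0 && owner[max(col)] != 0) {
      col <- sort(c(setdiff(col, cols[[owner[max(col)]]]),
                    setdiff(cols[[owner[max(col)]]], col)))
    }
    cols[[j]] <- col
    if (length(col) > 0) {
      low <- max(col)
      owner[low] <- j
      low_of[j] <- low
      pairs[[length(pairs) + 1]] <-
        c(dims[ord[low]], vals[ord[low]], vals[ord[j]])
    }
  }
  creators_unpaired <- which(low_of == 0 & owner == 0)
  ess <- lapply(creators_unpaired, function(jj) {
    c(dims[ord[jj]], vals[ord[jj]], Inf)
  })
  out <- do.call(rbind, c(pairs, ess))
  out <- data.frame(dim = out[, 1], birth = out[, 2], death = out[, 3])
  out$birth[out$dim == 0] <- 0
  out <- out[out$dim <= 1 & (out$death > out$birth), ]
  out[order(out$dim, out$birth, out$death), , drop = FALSE]
}

# number of connected components of the graph joining points at distance <=
# thresh (plain R union-find)
oracle_components <- function(D, thresh) {
  n <- nrow(D)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (D[i, j] <= thresh) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}

# partition from cutting the k-1 longest edges of the minimum spanning tree
oracle_mst_partition <- function(D, k) {
  st <- vegan::spantree(stats::as.dist(D))
  keep <- order(st$dist, decreasing = TRUE)[-seq_len(k - 1)]
  n <- nrow(D)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  kid <- as.integer(st$kid)
  for (e in keep) {
    a <- find(e + 1L); b <- find(kid[e])
    if (a != b) parent[b] <- a
  }
  vapply(seq_len(n), find, integer(1))
}

# two labellings describe the same partition
same_partition <- function(a, b) {
  length(unique(a)) == length(unique(b)) &&
    length(unique(paste(a, b))) == length(unique(a))
}

random_pattern <- function(n, seed, dom = domain(1000, 800), cell_type = "M") {
  set.seed(seed)
  point_pattern(data.frame(x = runif(n, 0, dom$length_x),
                           y = runif(n, 0, dom$length_y)),
                dom, cell_type = cell_type)
}

# a tiny snapshot with prescribed y bounds, for formation-time tests
snap_with_bounds <- function(day, y_min, y_max, dom = domain(1000, 3000)) {
  point_pattern(data.frame(x = c(100, 500, 900), y = c(y_min, (y_min + y_max) / 2, y_max)),
                dom, cell_type = "Xd", day = day)
}
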