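# Brute-force definitional MSPA classifier, written independently of the
# package internals: exhaustive pairwise distances, queue-based flood fills
# and explicit neighbour scans in plain R. It follows the same stated class
# definitions as the package (see the methods vignette) so the two routes
# must agree; it is deliberately slow and simple.

oracle_neighbors <- function(i, j, nr, nc, conn) {
  off <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  if (conn == 8)
    off <- c(off, list(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1)))
  out <- list()
  for (o in off) {
    ii <- i + o[1]; jj <- j + o[2]
    if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc)
      out[[length(out) + 1]] <- c(ii, jj)
  }
  out
}

# connected-component labels by BFS (pure R)
oracle_label <- function(mask, conn) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || lab[i, j] > 0L) next
    cur <- cur + 1L
    queue <- list(c(i, j))
    lab[i, j] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (nb in oracle_neighbors(p[1], p[2], nr, nc, conn)) {
        if (mask[nb[1], nb[2]] && lab[nb[1], nb[2]] == 0L) {
          lab[nb[1], nb[2]] <- cur
          queue <- c(queue, list(nb))
        }
      }
    }
  }
  lab
}

# squared euclidean (or plain chebyshev) distance from every cell to the
# nearest TRUE site, by exhaustive comparison
oracle_dist <- function(sites, metric) {
  nr <- nrow(sites); nc <- ncol(sites)
  out <- matrix(Inf, nr, nc)
  si <- which(sites, arr.ind = TRUE)
  if (nrow(si) == 0) return(out)
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    dr <- abs(si[, 1] - i); dc <- abs(si[, 2] - j)
    out[i, j] <- if (metric == "euclidean") min(dr^2 + dc^2)
                 else min(pmax(dr, dc))
  }
  out
}

# geodesic steps from sources within allowed cells (BFS, unit cost)
oracle_geodesic <- function(allowed, sources, conn) {
  nr <- nrow(allowed); nc <- ncol(allowed)
  d <- matrix(-1L, nr, nc)
  queue <- list()
  for (j in seq_len(nc)) for (i in seq_len(nr))
    if (sources[i, j] && allowed[i, j]) {
      d[i, j] <- 0L
      queue <- c(queue, list(c(i, j)))
    }
  while (length(queue)) {
    p <- queue[[1]]; queue <- queue[-1]
    for (nb in oracle_neighbors(p[1], p[2], nr, nc, conn)) {
      if (allowed[nb[1], nb[2]] && d[nb[1], nb[2]] < 0L) {
        d[nb[1], nb[2]] <- d[p[1], p[2]] + 1L
        queue <- c(queue, list(nb))
      }
    }
  }
  d
}

# Full definitional classification. Returns an integer matrix using the
# package's class codes (mspa_classes()).
oracle_mspa <- function(veg, edge_width = 2L, metric = "euclidean",
                        fgc = 8L, bgc = 4L) {
  codes <- mspa_classes()
  w <- edge_width
  pad <- w + 2L
  nr0 <- nrow(veg); nc0 <- ncol(veg)
  m <- matrix(FALSE, nr0 + 2L * pad, nc0 + 2L * pad)
  m[pad + seq_len(nr0), pad + seq_len(nc0)] <- veg
  nr <- nrow(m); nc <- ncol(m)
  bg <- !m
  lab <- matrix(codes[["background"]], nr, nc)
  thr <- if (metric == "euclidean") (w + 1)^2 else (w + 1)

  d_bg <- oracle_dist(bg, metric)
  core <- m & d_bg > thr

  patch <- oracle_label(m, fgc)
  islet <- m
  for (k in unique(patch[core])) islet[patch == k] <- FALSE
  islet <- islet & m
  rest <- m & !core & !islet

  lab[core] <- codes[["core"]]
  lab[islet] <- codes[["islet"]]

  if (any(rest)) {
    g <- oracle_geodesic(m, core, fgc)
    boundary <- rest & g > 0L & g <= (w + 1L)
    connector <- rest & !boundary

    bg_lab <- oracle_label(bg, bgc)
    ext <- unique(c(bg_lab[1, ], bg_lab[nr, ], bg_lab[, 1], bg_lab[, nc]))
    hole <- bg & !matrix(bg_lab %in% ext, nr, nc)
    lab[boundary] <- codes[["edge"]]
    if (any(hole)) {
      d_hole <- oracle_dist(hole, metric)
      d_open <- oracle_dist(bg & !hole, metric)
      lab[boundary & (d_hole < d_open)] <- codes[["perforation"]]
    }

    if (any(connector)) {
      core_lab <- oracle_label(core, fgc)
      # owner of each boundary/core pixel: nearest core component
      owner <- matrix(0L, nr, nc)
      owner[core] <- core_lab[core]
      bidx <- which(boundary, arr.ind = TRUE)
      ncore <- max(core_lab)
      if (nrow(bidx) && ncore > 0) {
        cidx <- which(core, arr.ind = TRUE)
        for (r in seq_len(nrow(bidx))) {
          dr <- abs(cidx[, 1] - bidx[r, 1]); dc <- abs(cidx[, 2] - bidx[r, 2])
          dd <- if (metric == "euclidean") dr^2 + dc^2 else pmax(dr, dc)
          best <- min(dd)
          owner[bidx[r, 1], bidx[r, 2]] <-
            min(core_lab[core][dd == best])
        }
      }
      conn_lab <- oracle_label(connector, fgc)
      for (comp in seq_len(max(conn_lab))) {
        pix <- which(conn_lab == comp, arr.ind = TRUE)
        touched <- integer()
        contact <- matrix(FALSE, nr, nc)
        for (r in seq_len(nrow(pix))) {
          ids <- integer()
          for (nb in oracle_neighbors(pix[r, 1], pix[r, 2], nr, nc, fgc)) {
            o <- owner[nb[1], nb[2]]
            if (o > 0L) ids <- c(ids, o)
          }
          if (length(ids)) {
            touched <- union(touched, ids)
            contact[pix[r, 1], pix[r, 2]] <- TRUE
          }
        }
        cls <- if (length(touched) >= 2L) codes[["bridge"]]
        else if (length(touched) == 1L) {
          n_stretch <- max(oracle_label(contact, fgc))
          if (n_stretch >= 2L) codes[["loop"]] else codes[["branch"]]
        } else codes[["branch"]]
        lab[conn_lab == comp] <- cls
      }
    }
  }
  lab[pad + seq_len(nr0), pad + seq_len(nc0), drop = FALSE]
}
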