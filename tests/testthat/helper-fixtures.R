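# Shared fixtures and reference oracles. Computed once per test run.

# The default 8-slice + 2-vesicle template (512 x 512 background).
tpl <- make_default_template()

# A small custom document: one rectangular slice covering (0,0,100,100)
# with slice factor `factor`, on a 100 x 100 background, plus `foci`
# (list of two-column vertex matrices) drawn as PCa foci on it.
rect_slice_doc <- function(foci = list(), factor = 1,
                           prostat_volumen = NA_real_,
                           complete = TRUE) {
  bg <- background_from_array(array(1, dim = c(100, 100, 3)))
  slice <- mask_surface("S1", shape = "rectangle",
                        rect = c(0, 0, 100, 100), percentage = factor)
  objs <- lapply(seq_along(foci), function(i) {
    map_object(paste0("F", i), tool_name = "PCa", kind = "pca_focus",
               geometry = foci[[i]], surface_id = "S1",
               befund = befund_record(paste0("F", i), gleason1 = 3,
                                      gleason2 = 4))
  })
  cmdx_document(
    mask = list(slice),
    tools = list(draw_tool("PCa", type = "Polygon")),
    background = bg, map_objects = objs,
    form = form_record(prostat_volumen = prostat_volumen),
    complete = complete)
}

square_pts <- function(x, y, side) {
  rbind(c(x, y), c(x + side, y), c(x + side, y + side), c(x, y + side))
}

# Brute-force flood-fill reference: queue-based BFS over the same
# Chebyshev colour criterion, independent of the package implementation.
bfs_flood_fill <- function(image, seed, tolerance = 0) {
  chans <- if (is.matrix(image)) list(image) else
    lapply(seq_len(min(dim(image)[3], 3)), function(i) image[, , i])
  h <- nrow(chans[[1]]); w <- ncol(chans[[1]])
  x0 <- seed[1] + 1L; y0 <- seed[2] + 1L
  ok <- matrix(TRUE, h, w)
  for (ch in chans) {
    ok <- ok & (abs(ch - ch[y0, x0]) * 255 <= tolerance + 1e-9)
  }
  seen <- matrix(FALSE, h, w)
  queue <- list(c(y0, x0))
  seen[y0, x0] <- TRUE
  while (length(queue)) {
    p <- queue[[length(queue)]]
    queue[[length(queue)]] <- NULL
    for (dy in -1:1) for (dx in -1:1) {
      if (dy == 0 && dx == 0) next
      r <- p[1] + dy; c_ <- p[2] + dx
      if (r < 1 || r > h || c_ < 1 || c_ > w) next
      if (seen[r, c_] || !ok[r, c_]) next
      seen[r, c_] <- TRUE
      queue[[length(queue) + 1L]] <- c(r, c_)
    }
  }
  seen
}

# Brute-force hole filling: BFS from every border background pixel with
# 4-connectivity; anything not reached is foreground or hole.
bfs_fill_holes <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  seen <- matrix(FALSE, h, w)
  queue <- list()
  for (r in seq_len(h)) for (c_ in c(1L, w)) {
    if (!mask[r, c_] && !seen[r, c_]) {
      seen[r, c_] <- TRUE; queue[[length(queue) + 1L]] <- c(r, c_)
    }
  }
  for (c_ in seq_len(w)) for (r in c(1L, h)) {
    if (!mask[r, c_] && !seen[r, c_]) {
      seen[r, c_] <- TRUE; queue[[length(queue) + 1L]] <- c(r, c_)
    }
  }
  while (length(queue)) {
    p <- queue[[length(queue)]]
    queue[[length(queue)]] <- NULL
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      r <- p[1] + d[1]; c_ <- p[2] + d[2]
      if (r < 1 || r > h || c_ < 1 || c_ > w) next
      if (seen[r, c_] || mask[r, c_]) next
      seen[r, c_] <- TRUE
      queue[[length(queue) + 1L]] <- c(r, c_)
    }
  }
  !seen
}

# Brute-force transitive closure of a symmetric overlap matrix; returns
# an integer partition label per element.
closure_partition <- function(adj) {
  n <- nrow(adj)
  reach <- adj | diag(TRUE, n)
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  labels <- integer(n)
  k <- 0L
  for (i in seq_len(n)) {
    if (labels[i] == 0L) {
      k <- k + 1L
      labels[reach[i, ]] <- k
    }
  }
  labels
}

# Canonical form of a partition given as per-element labels: sorted list
# of sorted member index vectors (label-renaming invariant).
canon_partition <- function(labels) {
  parts <- unname(split(seq_along(labels), labels))
  parts <- lapply(parts, sort)
  parts[order(vapply(parts, `[`, numeric(1), 1))]
}
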