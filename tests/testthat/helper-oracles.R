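# Independent oracles and geometric fixtures, implemented without the
# package's own routines so they can check them.

# Rasterized annulus: TRUE where rInner <= distance(center) <= rOuter.
annulus_mask <- function(n, center, rInner, rOuter) {
  d <- sqrt(outer((seq_len(n) - center[1])^2, (seq_len(n) - center[2])^2, "+"))
  d >= rInner & d <= rOuter
}

disk_mask <- function(n, center, r) annulus_mask(n, center, 0, r)

# Exhaustive BFS connected-component labeling (8- or 4-connectivity).
bfs_label <- function(mask, eight = TRUE) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nb <- if (eight) expand.grid(di = -1:1, dj = -1:1) else
    data.frame(di = c(-1, 1, 0, 0), dj = c(0, 0, -1, 1))
  nb <- nb[!(nb$di == 0 & nb$dj == 0), ]
  nxt <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || lab[i, j]) next
    nxt <- nxt + 1L
    queue <- list(c(i, j)); lab[i, j] <- nxt
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(nb))) {
        qi <- p[1] + nb$di[k]; qj <- p[2] + nb$dj[k]
        if (qi < 1 || qi > nr || qj < 1 || qj > nc) next
        if (mask[qi, qj] && !lab[qi, qj]) {
          lab[qi, qj] <- nxt
          queue[[length(queue) + 1L]] <- c(qi, qj)
        }
      }
    }
  }
  lab
}

# Hole filling by BFS from the border over 4-connected background.
bfs_fill <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  outside <- matrix(FALSE, nr, nc)
  queue <- list()
  push <- function(i, j) {
    if (!mask[i, j] && !outside[i, j]) {
      outside[i, j] <<- TRUE
      queue[[length(queue) + 1L]] <<- c(i, j)
    }
  }
  for (i in seq_len(nr)) { push(i, 1L); push(i, nc) }
  for (j in seq_len(nc)) { push(1L, j); push(nr, j) }
  while (length(queue)) {
    p <- queue[[1]]; queue <- queue[-1]
    if (p[1] > 1) push(p[1] - 1L, p[2])
    if (p[1] < nr) push(p[1] + 1L, p[2])
    if (p[2] > 1) push(p[1], p[2] - 1L)
    if (p[2] < nc) push(p[1], p[2] + 1L)
  }
  !outside
}

# Brute-force Mann-Whitney: U by definition (pairwise comparisons) and the
# exact two-sided p by enumerating every assignment of the pooled values.
brute_u <- function(g1, g2) {
  sum(outer(g1, g2, ">")) + 0.5 * sum(outer(g1, g2, "=="))
}

brute_exact_p <- function(g1, g2) {
  pooled <- c(g1, g2)
  n1 <- length(g1)
  idx <- utils::combn(length(pooled), n1)
  us <- apply(idx, 2, function(k) brute_u(pooled[k], pooled[-k]))
  u_obs <- brute_u(g1, g2)
  u_min <- min(u_obs, n1 * length(g2) - u_obs)
  min(1, 2 * mean(us <= u_min))
}

# Relative error helper (percent).
rel_err_pct <- function(got, want) 100 * abs(got - want) / want

# Compartment areas recovered by the pipeline, as a named vector.
seg_areas <- function(seg) {
  c(media = sum(mediaMask(seg)), internal = sum(internalMask(seg)),
    lumen = sum(lumenMask(seg)), plaque = plaquePixelCount(seg),
    lipid = sum(lipidMask(seg)), collagen = sum(collagenMask(seg)))
}

truth_areas <- function(truth) {
  a <- truth@areasPx
  c(media = a[["media"]], internal = a[["internal"]], lumen = a[["lumen"]],
    plaque = a[["plaque"]], lipid = a[["lipid"]], collagen = a[["collagen"]])
}

# Printed per-section legend areas (um^2) used as fixed external inputs:
# automatic vs manual measurements of one proximal and one distal section.
legend_areas <- list(
  proximal_auto = list(media = 161749, lumen = 36900, plaque = 283017,
                       collagen = 41446, lipid = 37317,
                       rel = c(media = 33.58, lumen = 7.66, plaque = 58.75,
                               collagen = 14.64, lipid = 13.18)),
  proximal_manual = list(media = 155723, lumen = 38097, plaque = 285795,
                         collagen = NA, lipid = 39553,
                         rel = c(media = 32.46, lumen = 7.94, plaque = 59.58,
                                 collagen = NA, lipid = 13.83)),
  distal_auto = list(media = 130864, lumen = 55146, plaque = 224918,
                     collagen = 18018, lipid = 33820,
                     rel = c(media = 31.84, lumen = 13.42, plaque = 54.73,
                             collagen = 8.01, lipid = 15.03)),
  distal_manual = list(media = 128424, lumen = 57445, plaque = 225778,
                       collagen = NA, lipid = 34781,
                       rel = c(media = 31.19, lumen = 13.95, plaque = 54.84,
                               collagen = NA, lipid = 15.4))
)

legend_record <- function(x, id = "s", label = "unspecified") {
  morphometryFromAreas(x$media, x$lumen, x$plaque, x$collagen, x$lipid,
                       sectionId = id, segmentLabel = label)
}
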