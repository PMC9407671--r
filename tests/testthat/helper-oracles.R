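# Independent brute-force oracles and shared fixtures for the test suite.
# The oracles deliberately avoid the package's neighbor-search and scoring
# code paths: plain double loops over all pairs.

## all pairs within cutoff, nested loops
bf_pairs <- function(a, b, cutoff) {
  a <- as.matrix(a); b <- as.matrix(b)
  out <- list()
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      d <- sqrt(sum((a[i, ] - b[j, ])^2))
      if (d <= cutoff) out[[length(out) + 1]] <- c(i, j, d)
    }
  }
  if (length(out) == 0) {
    return(data.frame(i = integer(0), j = integer(0), d = numeric(0)))
  }
  m <- do.call(rbind, out)
  data.frame(i = m[, 1], j = m[, 2], d = m[, 3])
}

## hard/soft clash counts, all pairs
bf_clash_counts <- function(at_a, at_b) {
  vdw <- c(C = 1.7, N = 1.55, O = 1.52, S = 1.8)
  radius <- function(e) ifelse(is.na(vdw[e]), 1.7, vdw[e])
  at_a <- at_a[!(at_a$elesy %in% c("H", "D")), ]
  at_b <- at_b[!(at_b$elesy %in% c("H", "D")), ]
  hard <- 0L; soft <- 0L
  for (i in seq_len(nrow(at_a))) {
    for (j in seq_len(nrow(at_b))) {
      d <- sqrt((at_a$x[i] - at_b$x[j])^2 + (at_a$y[i] - at_b$y[j])^2 +
                  (at_a$z[i] - at_b$z[j])^2)
      if (d < 2.5) {
        hard <- hard + 1L
      } else if (d < 0.8 * (radius(at_a$elesy[i]) + radius(at_b$elesy[j]))) {
        soft <- soft + 1L
      }
    }
  }
  c(hard = hard, soft = soft)
}

## backbone H-bond detection, all pairs, same geometric criteria as the
## package but re-derived with plain loops (one best acceptor per donor)
bf_hbonds <- function(donors, acceptors, dist_cutoff = 3.5, angle_cutoff = 120) {
  hits <- list()
  for (i in seq_len(nrow(donors$df))) {
    if (donors$df$resid[i] == "PRO" || is.na(donors$H[i, 1])) next
    best <- NULL
    for (j in seq_len(nrow(acceptors$df))) {
      if (donors$df$chain[i] == acceptors$df$chain[j] &&
          abs(donors$df$pos[i] - acceptors$df$pos[j]) <= 2) next
      d <- sqrt(sum((donors$N[i, ] - acceptors$O[j, ])^2))
      if (d > dist_cutoff) next
      v1 <- donors$N[i, ] - donors$H[i, ]
      v2 <- acceptors$O[j, ] - donors$H[i, ]
      ang <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
      if (ang < angle_cutoff) next
      if (is.null(best) || d < best$d ||
          (d == best$d && acceptors$df$pos[j] < best$jpos)) {
        best <- list(i = i, j = j, d = d, jpos = acceptors$df$pos[j])
      }
    }
    if (!is.null(best)) hits[[length(hits) + 1]] <- best
  }
  hits
}

## deterministic random rotation matrix
random_rotation <- function(seed) {
  set.seed(seed)
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  ang <- runif(1, 10, 350)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(ang * pi / 180) * K + (1 - cos(ang * pi / 180)) * (K %*% K)
}

## shared fibril fixture (built once per test run)
.fixture_cache <- new.env(parent = emptyenv())

fib_fixture <- function() {
  if (is.null(.fixture_cache$fx)) {
    fx <- make_ideal_fibril(fibril_spec())
    asm <- group_layers(fx$model)
    sites <- enumerate_sites(asm, 1, "plus", window = 6)
    capper <- make_complementary_capper(sites[1, ], asm, body_class = "EEH",
                                        seed = 5)
    pose <- graft_scaffold(capper, 1, sites[1, ], asm)
    .fixture_cache$fx <- list(fx = fx, asm = asm, sites = sites,
                              capper = capper, pose = pose)
  }
  .fixture_cache$fx
}

## capper variant whose body backbone is overwritten with coordinates of
## the fibril's own tip layer, so that after grafting (an identity
## placement: the strand is untouched) the body overlaps the fibril
## (deterministic hard-clash fixture)
clash_capper_body <- function(capper, asm, site) {
  el <- capper$elements
  g <- which(el$kind == "E")[1]
  strand_idx <- el$start[g]:el$end[g]
  body_idx <- setdiff(seq_len(n_res(capper$bb)), strand_idx)
  ids <- asm$protofilaments[[site$protofilament]]
  tip <- if (site$fib_end == "plus") ids[length(ids)] else ids[1]
  src <- chain_backbone(asm$model, tip)$bb
  n_src <- n_res(src)
  for (k in seq_along(body_idx)) {
    j <- (k - 1) %% n_src + 1
    for (atom in c("N", "CA", "C", "O")) {
      capper$bb[[atom]][body_idx[k], ] <- src[[atom]][j, ]
    }
  }
  capper
}
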