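# Shared fixtures: all synthetic, built in code at test time.

# A donor-grouped 3:1:1 split over a bag set (first 3/5 of donors train,
# next 1/5 validation, rest test).
grouped_split <- function(bag_set) {
  don <- unique(bag_set$bags$donor_id)
  n <- length(don)
  cut1 <- ceiling(0.6 * n); cut2 <- ceiling(0.8 * n)
  list(train = bag_set$bags$bag_id[bag_set$bags$donor_id %in% don[1:cut1]],
       val = bag_set$bags$bag_id[bag_set$bags$donor_id %in% don[(cut1 + 1):cut2]],
       test = bag_set$bags$bag_id[bag_set$bags$donor_id %in% don[(cut2 + 1):n]])
}

# Attention parameters of a given geometry, seeded.
make_attn_weights <- function(embed_dim = 8, attn_dim = 4, seed = 42) {
  withr::with_seed(seed, list(
    V = matrix(rnorm(attn_dim * embed_dim), attn_dim, embed_dim),
    U = matrix(rnorm(attn_dim * embed_dim), attn_dim, embed_dim),
    w = rnorm(attn_dim)))
}

# Binary mask of a filled disk on an H x W canvas.
disk_mask <- function(H, W, cy, cx, r) {
  y <- matrix(seq_len(H), H, W)
  x <- matrix(seq_len(W), H, W, byrow = TRUE)
  (x - cx)^2 + (y - cy)^2 <= r^2
}

# Annulus (ring) mask.
ring_mask <- function(H, W, cy, cx, r_out, r_in) {
  disk_mask(H, W, cy, cx, r_out) & !disk_mask(H, W, cy, cx, r_in)
}

# Flat RGB canvas.
flat_image <- function(H, W, col = c(0.9, 0.85, 0.88)) {
  img <- array(0, c(H, W, 3))
  for (k in 1:3) img[, , k] <- col[k]
  img
}

# Brute-force weighted pairwise Mann-Whitney AUC (independent oracle).
pairwise_wauc <- function(score, pos, w) {
  ip <- which(pos); ineg <- which(!pos)
  num <- 0
  for (i in ip) for (j in ineg) {
    num <- num + w[i] * w[j] *
      ((score[i] > score[j]) + 0.5 * (score[i] == score[j]))
  }
  num / (sum(w[ip]) * sum(w[ineg]))
}

# A tissue_instance wrapper around a raw mask.
as_instance <- function(mask, class_label = "tubule", id = 1L) {
  structure(list(instance_id = id, class_label = class_label, mask = mask),
            class = "tissue_instance")
}
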