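#' Configuration for a synthetic multi-instance bag dataset
#'
#' Describes a desk-scale stand-in for slide-level prediction tasks: bags
#' of feature vectors with known positive-instance structure, controllable
#' contamination by corrupted instances, per-instance segmentation-noise
#' proxies (`sigma2`), and donor grouping for leakage-safe splits.
#'
#' Corrupted instances model two failure modes at once: their features are
#' shifted along a direction correlated with the *wrong* class (misleading
#' evidence) and their `sigma2` is drawn from a strictly higher-mean
#' distribution than clean instances (high ensemble disagreement), so the
#' benefit of quality weighting is testable as one controlled contrast.
#'
#' @param n_bags Number of bags.
#' @param instances_per_bag Range `(min, max)` of instances per bag.
#' @param dim Feature dimension.
#' @param effect Signal effect size: signal instances are shifted by
#'   `effect` along a fixed unit direction.
#' @param contamination Probability that a non-signal instance is
#'   corrupted, in `[0, 1)`.
#' @param n_donors Number of donors; donor ids partition bags.
#' @param mode `"binary"` (standard MIL rule: positive iff >= 1 signal
#'   instance) or `"ordinal"` (3 classes keyed to the signal-instance
#'   count: <7, 7-9, >= 10, mirroring a glomeruli-adequacy grading).
#' @param signal_per_bag Range of signal instances in a positive bag
#'   (binary mode).
#' @param sigma2_clean,sigma2_corrupt Gamma `(shape, rate)` of the
#'   per-instance disagreement proxy for clean and corrupted instances;
#'   defaults give means 0.01 and 0.1.
#' @param require_separable If `TRUE`, refuse configurations that cannot
#'   produce separable bags (effect size 0).
#' @param seed Integer seed.
#' @return A list of class `bag_config`.
#' @export
bag_config <- function(n_bags = 200L, instances_per_bag = c(8L, 16L),
                       dim = 10L, effect = 3, contamination = 0,
                       n_donors = 20L, mode = c("binary", "ordinal"),
                       signal_per_bag = c(1L, 4L),
                       sigma2_clean = c(4, 400), sigma2_corrupt = c(4, 40),
                       require_separable = TRUE, seed = 1L) {
  mode <- match.arg(mode)
  if (contamination < 0 || contamination >= 1) {
    stop("`contamination` must be in [0, 1)", call. = FALSE)
  }
  if (effect < 0) stop("`effect` must be >= 0", call. = FALSE)
  if (n_donors < 2L) stop("need >= 2 donors", call. = FALSE)
  if (effect == 0 && require_separable) {
    stop("effect size 0 cannot produce separable bags; set require_separable = FALSE",
         call. = FALSE)
  }
  structure(as.list(environment()), class = "bag_config")
}

#' Generate a synthetic bag dataset
#'
#' Background instances are drawn from a standard multivariate normal;
#' signal instances are shifted by the effect size along a fixed unit
#' direction; corrupted instances are shifted along the conflicting
#' direction (towards the signature of the wrong class for their bag) and
#' flagged with high `sigma2`. Binary labels follow the standard MIL rule;
#' ordinal mode assigns 3 classes by signal-instance count (<7, 7-9,
#' >= 10). Donors partition bags. Pure function of the config (which
#' carries the seed).
#'
#' @param config A [bag_config()].
#' @return A list of class `bag_set` with tibbles `instances`
#'   (`bag_id`, `instance_id`, `role`, `sigma2`, `f_1` ... `f_D`) and
#'   `bags` (`bag_id`, `donor_id`, `label`, `n_instances`), plus the
#'   config.
#' @export
synth_bags <- function(config) {
  stopifnot(inherits(config, "bag_config"))
  D <- as.integer(config$dim)
  u <- rep(1 / sqrt(D), D)   # fixed signal direction
  with_seed(config$seed, {
    n <- as.integer(config$n_bags)
    # consecutive bags share a donor so each donor sees a label mix
    donors <- paste0("donor_",
                     ((seq_len(n) - 1L) %/% ceiling(n / config$n_donors)) + 1L)
    if (config$mode == "binary") {
      labels <- rep_len(c(0L, 1L), n)
    } else {
      n_signal_all <- sample(2:14, n, replace = TRUE)
      labels <- as.integer(cut(n_signal_all, c(-Inf, 6.5, 9.5, Inf))) - 1L
    }
    inst_rows <- vector("list", n)
    for (b in seq_len(n)) {
      if (config$mode == "binary") {
        K <- sample(seq(config$instances_per_bag[1], config$instances_per_bag[2]), 1L)
        ns <- if (labels[b] == 1L) {
          min(K, sample(seq(config$signal_per_bag[1], config$signal_per_bag[2]), 1L))
        } else 0L
      } else {
        # ordinal mode: the signal count drives the class; the total bag
        # size is held constant so the count is identifiable from the
        # signal fraction, which is what attention pooling observes
        ns <- n_signal_all[b]
        K <- max(config$instances_per_bag[2], max(n_signal_all) + 2L)
      }
      role <- c(rep("signal", ns), rep("background", K - ns))
      corrupt <- role == "background" & stats::runif(K) < config$contamination
      role[corrupt] <- "corrupted"
      X <- matrix(stats::rnorm(K * D), K, D)
      if (ns > 0L) X[role == "signal", ] <-
          X[role == "signal", , drop = FALSE] + rep(config$effect * u, each = ns)
      if (any(corrupt)) {
        # artefacts mimic the positive signature irrespective of the bag
        # label, so in negative bags they carry evidence correlated with
        # the wrong class — the case that sways bag-level predictions
        X[corrupt, ] <- X[corrupt, , drop = FALSE] +
          rep(config$effect * u, each = sum(corrupt))
      }
      s2 <- ifelse(role == "corrupted",
                   stats::rgamma(K, config$sigma2_corrupt[1], config$sigma2_corrupt[2]),
                   stats::rgamma(K, config$sigma2_clean[1], config$sigma2_clean[2]))
      colnames(X) <- paste0("f_", seq_len(D))
      inst_rows[[b]] <- dplyr::bind_cols(
        tibble::tibble(bag_id = b, instance_id = seq_len(K),
                       role = role, sigma2 = s2),
        tibble::as_tibble(X))
    }
    instances <- dplyr::bind_rows(inst_rows)
    bags <- tibble::tibble(
      bag_id = seq_len(n), donor_id = donors, label = labels,
      n_instances = as.integer(table(factor(instances$bag_id, levels = seq_len(n)))))
    structure(list(instances = instances, bags = bags, config = config),
              class = "bag_set")
  })
}

#' Per-bag quality weights from the disagreement proxy
#'
#' Applies the per-slide quality-weight rule to the `sigma2` column of a
#' bag set: within each bag, `g = (max s2 - s2) / (max s2 - min s2)`, with
#' all weights 1 when every `s2` in the bag is equal.
#'
#' @param bag_set A [synth_bags()] result.
#' @return The bag set with a `g` column added to `$instances`.
#' @export
bag_quality_weights <- function(bag_set) {
  stopifnot(inherits(bag_set, "bag_set"))
  bag_set$instances <- bag_set$instances |>
    dplyr::group_by(.data$bag_id) |>
    dplyr::mutate(g = quality_weight_rule(.data$sigma2)) |>
    dplyr::ungroup()
  bag_set
}

#' Write a bag set as two delimited tables
#'
#' `instances.csv` holds `bag_id, instance_id, role, sigma2, f_*` (and `g`
#' if present); `bags.csv` holds `bag_id, donor_id, label, n_instances`.
#'
#' @param bag_set A `bag_set`.
#' @param path Directory to write into.
#' @return Invisibly, the directory.
#' @export
write_bags <- function(bag_set, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(bag_set$instances, file.path(path, "instances.csv"),
                   row.names = FALSE)
  utils::write.csv(bag_set$bags, file.path(path, "bags.csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname write_bags
#' @export
read_bags <- function(path) {
  instances <- tibble::as_tibble(utils::read.csv(file.path(path, "instances.csv")))
  bags <- tibble::as_tibble(utils::read.csv(file.path(path, "bags.csv")))
  structure(list(instances = instances, bags = bags, config = NULL),
            class = "bag_set")
}

#' @export
print.bag_set <- function(x, ...) {
  cat("<bag_set> ", nrow(x$bags), " bags, ",
      nrow(x$instances), " instances, ",
      length(unique(x$bags$donor_id)), " donors\n", sep = "")
  print(dplyr::count(x$bags, .data$label))
  invisible(x)
}
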