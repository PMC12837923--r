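#' Describe an experiment schedule
#'
#' A design spec fixes the stimulus grid (categories x images), the
#' presentation conditions, the number of blocks and whether the
#' category-to-presentation assignment is counterbalanced across the two
#' halves of the session. Counterbalancing requires an even category
#' count, an even block count and exactly two presentation conditions:
#' in the first half of the blocks half the categories are bound to the
#' first presentation time and the rest to the second, with the mapping
#' reversed in the second half.
#'
#' @param categories Ordered character vector of category labels.
#' @param n_images_per_category Images per category (default 30).
#' @param presentations Presentation conditions used
#'   (subset of `"ms50"`, `"ms200"`, `"self_paced"`).
#' @param n_blocks Number of blocks.
#' @param counterbalance Counterbalance categories across presentations?
#' @param image_condition Image condition label for every trial.
#' @param seed Integer seed controlling trial order.
#' @return An object of class `design_spec`.
#' @export
#' @examples
#' # two-duration design: 10 categories x 60 images x 2 presentations,
#' # 8 blocks, counterbalanced
#' design_spec(sprintf("cat%02d", 1:10), 60, c("ms50", "ms200"),
#'             n_blocks = 8, counterbalance = TRUE)
design_spec <- function(categories = default_categories(),
                        n_images_per_category = 30,
                        presentations = "ms50",
                        n_blocks = 6,
                        counterbalance = FALSE,
                        image_condition = "full",
                        seed = 1L) {
  stopifnot(is.character(categories), length(categories) >= 2,
            !anyDuplicated(categories),
            n_images_per_category >= 1, n_blocks >= 1,
            all(presentations %in% setdiff(PRESENTATIONS, "none")),
            !anyDuplicated(presentations),
            image_condition %in% IMAGE_CONDITIONS)
  if (counterbalance) {
    if (length(categories) %% 2 != 0)
      stop("configuration error: counterbalancing needs an even number ",
           "of categories", call. = FALSE)
    if (n_blocks %% 2 != 0)
      stop("configuration error: counterbalancing needs an even number ",
           "of blocks", call. = FALSE)
    if (length(presentations) != 2)
      stop("configuration error: counterbalancing needs exactly two ",
           "presentation conditions", call. = FALSE)
  }
  structure(list(categories = categories,
                 n_images_per_category = as.integer(n_images_per_category),
                 presentations = presentations,
                 n_blocks = as.integer(n_blocks),
                 counterbalance = isTRUE(counterbalance),
                 image_condition = image_condition,
                 seed = as.integer(seed)),
            class = "design_spec")
}

design_stimuli <- function(spec) {
  data.frame(
    stimulus_id = as.vector(vapply(spec$categories, function(cat)
      sprintf("%s_%03d", cat, seq_len(spec$n_images_per_category)),
      character(spec$n_images_per_category))),
    true_category = rep(spec$categories, each = spec$n_images_per_category),
    stringsAsFactors = FALSE)
}

# Deal a shuffled trial pool into n_blocks blocks whose sizes differ by
# at most one, assigning global trial indices in block order.
deal_blocks <- function(trials, n_blocks, block_offset = 0L) {
  n <- nrow(trials)
  sizes <- rep(n %/% n_blocks, n_blocks)
  if (n %% n_blocks) sizes[seq_len(n %% n_blocks)] <-
      sizes[seq_len(n %% n_blocks)] + 1L
  trials$block <- block_offset + rep(seq_len(n_blocks), times = sizes)
  trials
}

#' Build a randomised (optionally counterbalanced) trial schedule
#'
#' Every stimulus occurs exactly once per presentation condition. With
#' counterbalancing on, each category is bound to a single presentation
#' time within the first half of the blocks and to the other presentation
#' in the second half, so repeated images always switch duration between
#' halves. Trial order within blocks is randomised by the spec's seed;
#' block sizes differ by at most one trial.
#'
#' @param spec A [design_spec()].
#' @return Data frame with columns `block`, `trial_index`, `stimulus_id`,
#'   `true_category`, `presentation`, `image_condition`, ordered by
#'   `trial_index`.
#' @export
#' @examples
#' d <- design_spec(sprintf("c%d", 1:10), 60, c("ms50", "ms200"),
#'                  n_blocks = 8, counterbalance = TRUE)
#' sched <- make_counterbalanced_design(d)
#' nrow(sched)        # 1200 trials
#' table(sched$block) # 150 per block
make_counterbalanced_design <- function(spec) {
  stopifnot(inherits(spec, "design_spec"))
  stimuli <- design_stimuli(spec)
  with_seed(spec$seed, {
    if (spec$counterbalance) {
      k <- length(spec$categories)
      first_set <- spec$categories[seq_len(k / 2)]
      halves <- lapply(1:2, function(h) {
        pres <- ifelse(stimuli$true_category %in% first_set,
                       spec$presentations[h], spec$presentations[3 - h])
        pool <- cbind(stimuli, presentation = pres,
                      stringsAsFactors = FALSE)
        pool <- pool[sample.int(nrow(pool)), , drop = FALSE]
        deal_blocks(pool, spec$n_blocks %/% 2L,
                    block_offset = as.integer((h - 1) * spec$n_blocks / 2))
      })
      sched <- rbind(halves[[1]], halves[[2]])
    } else {
      pool <- do.call(rbind, lapply(spec$presentations, function(p)
        cbind(stimuli, presentation = p, stringsAsFactors = FALSE)))
      pool <- pool[sample.int(nrow(pool)), , drop = FALSE]
      sched <- deal_blocks(pool, spec$n_blocks)
    }
    sched <- sched[order(sched$block), , drop = FALSE]
    sched$trial_index <- seq_len(nrow(sched))
    sched$image_condition <- spec$image_condition
    rownames(sched) <- NULL
    sched[c("block", "trial_index", "stimulus_id", "true_category",
            "presentation", "image_condition")]
  })
}
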