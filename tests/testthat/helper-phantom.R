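# Small, fast phantom configurations shared across test files. The
# coarser-than-default spacings keep unit tests quick; acceptance tests
# use package defaults.

small_config <- function(seed = 1, ...) {
  args <- list(seed = seed, half_axes = c(8, 7, 10),
               tumor_center = c(1, 1.5, 0), tumor_axes = c(3.5, 3, 4.5),
               us_spacing = c(0.3, 0.3, 0.5), histo_spacing = c(0.15, 0.15))
  do.call(phantom_config, utils::modifyList(args, list(...)))
}

# one shared identity-transform phantom and one shrunk phantom, built once
PH0 <- phantom_specimen(small_config(seed = 11, shrinkage = 0))
PH2 <- phantom_specimen(small_config(seed = 12, shrinkage = 0.2))

# all tumor-bearing slides of a phantom with their partitions, as a list
tumor_slides <- function(ph) {
  stk <- ph$stack
  idx <- which(vapply(stk$slides, function(m) any(m == 2L), TRUE))
  lapply(idx, function(i) {
    list(slide = i, mask = stk$slides[[i]], edges = stk$mucosal_edges[[i]],
         spacing = stk$spacing, origin = stk$origin,
         orientation = stk$orientation)
  })
}
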