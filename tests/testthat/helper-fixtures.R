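# Shared fixtures, memoized across test files (generation is the slow
# part, not the assertions).

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, maker) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- maker()
  .fixtures[[name]]
}

# 5 patients per class, 6 slices, full 256x256 world
small_patients <- function() fixture("small_patients", function()
  make_dataset(5, n_slices = 6, seed = 301))

small_items <- function() fixture("small_items", function()
  encode_dataset(small_patients()))

# cheap labeled dummy thickness images (episode sampling only looks at
# the condition label)
dummy_items <- function(n_per_class = 20) {
  out <- list()
  for (cl in condition_classes())
    for (i in seq_len(n_per_class))
      out[[length(out) + 1]] <- thickness_image(
        sprintf("%s%02d", cl, i),
        array(i %% 256L, c(4, 2, 3)), condition = cl)
  out
}

# tiny but trainable configuration used by smoke/determinism tests
tiny_config <- function(seed = 5, ...)
  few_shot_config(k_shot = 3, m_query = 2, episodes_per_epoch = 3,
                  epochs = 1, subspace_rank = 2, seed = seed, ...)

tiny_encoder_args <- list(filters = c(2L, 2L, 2L, 2L), input_pool = 4L)

# random orthonormal D x r basis
random_basis <- function(d, r) qr.Q(qr(matrix(stats::rnorm(d * r), d, r)))
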