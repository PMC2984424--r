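# shared simulation fixtures, built once per test run

.sim_cache <- new.env(parent = emptyenv())

ref_params <- function(...) model_params(...)

# reference-parameter run of the distributed-proliferation model
ref_kymo <- function() {
  if (is.null(.sim_cache$ref))
    .sim_cache$ref <- simulate_tissue(ref_params())
  .sim_cache$ref
}

# progress-zone (localized_age) run at the same constants
localized_kymo <- function() {
  if (is.null(.sim_cache$loc))
    .sim_cache$loc <- simulate_tissue(
      model_params(variant = "localized_age", n_cells = 400))
  .sim_cache$loc
}

# small, fast distributed run for plumbing tests
small_params <- function(...) {
  args <- utils::modifyList(list(t_end = 6, dt = 0.05, n_cells = 60),
                            list(...))
  do.call(model_params, args)
}

# hand-built kymograph with a prescribed frozen profile, for segment
# analysis unit tests (localized variant => mat is the lab coordinate and
# widths are direct spans)
synthetic_kymo <- function(mat, z_frozen, freeze_time,
                           freeze_phase = cumsum(rep(0.1, length(mat)))) {
  p <- model_params(variant = "localized_age", n_cells = 50)
  structure(list(
    times = c(0, max(freeze_time[is.finite(freeze_time)], 1)),
    space_bins = seq(0.5, max(mat), length.out = 10),
    z_grid = matrix(0, 2, 10),
    lengths = c(p$L0, p$L0 + max(freeze_time[is.finite(freeze_time)], 1)),
    frozen_front = matrix(NA_real_, 2, 2, dimnames = list(NULL, c("lo", "hi"))),
    cells = data.frame(mat = mat, birth = 0, freeze_time = freeze_time,
                       freeze_phase = freeze_phase, z_frozen = z_frozen),
    params = p), class = "kymograph")
}
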