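# Shared fixture builders. Everything is generated in code at test time.

# Minimal hand-sized metabolite tibble: 6 samples (3 case / 3 control).
toy_tibble <- function() {
  tibble::tibble(
    sample_id = sprintf("s%d", 1:6),
    group = rep(c("case", "control"), each = 3),
    metA = c(1, 2, 3, 4, 5, 6),
    metB = c(10, 20, 30, 40, 50, 60),
    metC = c(2, 2, 2, 2, 2, 2)
  )
}

# Two-group tibble with one perfectly separating metabolite (disjoint group
# supports) plus pure-noise metabolites.
separable_tibble <- function(n_case = 12, n_control = 27, n_noise = 5,
                             seed = 1) {
  withr::with_seed(seed, {
    n <- n_case + n_control
    out <- tibble::tibble(
      sample_id = sprintf("s%02d", seq_len(n)),
      group = rep(c("case", "control"), c(n_case, n_control)),
      sep = c(runif(n_case, 5, 6), runif(n_control, 8, 9))
    )
    for (j in seq_len(n_noise)) {
      out[[sprintf("noise%02d", j)]] <- rnorm(n)
    }
    out
  })
}

# A small toy GMT annotation written to a temp file; returns the path.
toy_gmt_path <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "toy.gmt")
  writeLines(c(
    "PW1\tPathway one\tm1\tm2\tm3\tm4\tm5",
    "PW2\tPathway two\tm6\tm7\tm8"
  ), path)
  path
}
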