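# A small two-class feature matrix with an optional mean shift on feature 1.
make_task_fm <- function(n_per_class = 40, p = 10, effect = 0, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(2 * n_per_class * p), 2 * n_per_class, p,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  x[(n_per_class + 1):(2 * n_per_class), 1] <-
    x[(n_per_class + 1):(2 * n_per_class), 1] + effect
  g <- rep(c("CN", "AD"), each = n_per_class)
  ids <- sprintf("x%03d", seq_len(2 * n_per_class))
  rownames(x) <- ids
  structure(list(values = x, labels = factor(g, levels = c("CN", "AD")),
                 subject_ids = ids, task = c("CN", "AD"),
                 split = rep(NA_character_, length(ids)), scaling = NULL),
            class = "feature_matrix")
}
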