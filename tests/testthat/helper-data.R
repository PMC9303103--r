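# Dataset fixtures built in code at test time.

# Small phantom dataset on disk; returns the manifest path.
make_tiny_dataset <- function(n_train = 8, n_val = 2, n_test = 2,
                              image_size = 64, seed = 11,
                              dir = withr::local_tempdir(.local_envir = parent.frame())) {
  cfg <- phantom_config(image_size = image_size, seed = seed)
  generate_dataset(cfg, n_train, n_val, n_test, dir)
}

# Manifest whose train/val splits repeat one phantom (overfit fixture).
make_repeated_sample_dataset <- function(n_rep = 8, image_size = 64, seed = 21,
                                         dir = withr::local_tempdir(.local_envir = parent.frame())) {
  s <- generate_sample(phantom_config(image_size = image_size, seed = seed), 1)
  dir.create(file.path(dir, "images"), showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), showWarnings = FALSE)
  png::writePNG(s$image, file.path(dir, "images", "a.png"))
  png::writePNG(s$mask / 255, file.path(dir, "masks", "a.png"))
  m <- do.call(rbind, lapply(seq_len(n_rep + 1), function(i) data.frame(
    id = paste0("a", i), split = if (i <= n_rep) "train" else "val",
    image = "images/a.png", mask = "masks/a.png")))
  path <- file.path(dir, "manifest.csv")
  utils::write.table(m, path, sep = ",", quote = FALSE, row.names = FALSE)
  path
}

tiny_model <- function(base_width = 8, depth = 2, seed = 1, ...) {
  model_config(base_width = base_width, depth = depth, seed = seed, ...)
}

short_stages <- function(e1 = 2, e2 = 2, gamma2 = 0, seed = 5,
                         lr1 = 2e-3, lr2 = 5e-4) {
  list(stage_config(1, lr_init = lr1, batch_size = 4, max_epochs = e1,
                    patience = max(2, e1), seed = seed),
       stage_config(2, lr_init = lr2, batch_size = 2, max_epochs = e2,
                    patience = max(2, e2),
                    weights = loss_weights(1, 1, gamma2, 4), seed = seed + 1))
}

read_log <- function(ckpt) {
  lapply(readLines(attr(ckpt, "log")), jsonlite::fromJSON)
}
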