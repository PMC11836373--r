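# Dataset serialization: directory-per-class grayscale PNGs with a
# manifest CSV. Pixel values map linearly to [0,1] on read and back on
# write; SMOTE-synthesized files are suffixed "_syn####" so provenance
# survives a round-trip.

#' Write a dataset as directory-per-class PNGs
#'
#' Creates one subdirectory per class under `path` and writes each image
#' as an 8-bit grayscale PNG (`img_####.png`, or `img_####_syn####.png`
#' for synthetic samples), plus a `manifest.csv` with columns
#' `filename,class,class_id,synthetic` (`class_id` is 0-based on disk).
#'
#' @param dataset an [oct_dataset()].
#' @param path output directory (created if absent).
#' @return `path`, invisibly.
#' @export
write_dataset_dir <- function(dataset, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  syn_counter <- 0L
  rows <- vector("list", length(dataset$labels))
  for (i in seq_along(dataset$labels)) {
    cls <- dataset$class_names[dataset$labels[i]]
    dir.create(file.path(path, cls), showWarnings = FALSE)
    if (dataset$synthetic[i]) {
      syn_counter <- syn_counter + 1L
      fname <- sprintf("img_%04d_syn%04d.png", i, syn_counter)
    } else {
      fname <- sprintf("img_%04d.png", i)
    }
    png::writePNG(dataset$images[[i]], file.path(path, cls, fname))
    rows[[i]] <- data.frame(filename = file.path(cls, fname), class = cls,
                            class_id = dataset$labels[i] - 1L,
                            synthetic = dataset$synthetic[i])
  }
  utils::write.csv(do.call(rbind, rows), file.path(path, "manifest.csv"),
                   row.names = FALSE)
  invisible(path)
}

#' Read a directory-per-class PNG dataset
#'
#' Reads every PNG under one subdirectory per class (classes sorted by
#' name unless `class_names` is given); multi-channel images are averaged
#' to grayscale. Files suffixed `_syn####` are flagged synthetic.
#'
#' @param path dataset directory.
#' @param class_names optional explicit class order.
#' @return an [oct_dataset()].
#' @export
read_dataset_dir <- function(path, class_names = NULL) {
  if (is.null(class_names)) {
    class_names <- sort(list.dirs(path, recursive = FALSE, full.names = FALSE))
  }
  if (length(class_names) == 0L) stopf("no class subdirectories under %s", path)
  images <- list(); labels <- integer(0); synthetic <- logical(0)
  for (c in seq_along(class_names)) {
    files <- sort(list.files(file.path(path, class_names[c]),
                             pattern = "\\.png$", full.names = TRUE))
    for (f in files) {
      img <- png::readPNG(f)
      if (length(dim(img)) == 3L) img <- apply(img, c(1, 2), mean)
      images[[length(images) + 1L]] <- img
      labels <- c(labels, c)
      synthetic <- c(synthetic, grepl("_syn[0-9]+\\.png$", basename(f)))
    }
  }
  oct_dataset(images, labels, class_names, synthetic)
}
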