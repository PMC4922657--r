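# Dataset container read/write and stimulus preprocessing. The on-disk
# container is a directory bundle: meta.json plus CSV arrays written at
# full precision ("%.17g"), which round-trips doubles bitwise while
# keeping the format plain text and tool-agnostic.
#
# Schema (all CSV without headers):
#   meta.json          p, n_train, m, n_val, n_trials, has_validation, meta
#   images.csv         n_train rows x p^2 columns (column-major pixel order:
#                      pixel (k, l), 0-based, at flat index l*p + k + 1)
#   train_responses.csv n_train x m
#   val_images.csv     n_val x p^2              (when validation present)
#   val_responses.csv  (n_val * n_trials) x m, trial-major blocks: the
#                      response of stimulus s, neuron j, trial t is at row
#                      (t-1)*n_val + s

write_num_csv <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(apply(x, 1, function(r) paste(sprintf("%.17g", r),
                                           collapse = ",")), con)
}

read_num_csv <- function(path) {
  x <- as.matrix(data.table::fread(path, header = FALSE,
                                   colClasses = "numeric"))
  dimnames(x) <- NULL
  x
}

#' Write / read a population dataset container
#'
#' Lossless, seed-free round trip: `read_dataset(write_dataset(ds, path))`
#' returns arrays bitwise-identical to `ds`. The container is a directory
#' holding `meta.json` and full-precision CSV arrays (see the package
#' source for the exact schema). A container without a validation set
#' loads with validation marked absent; evaluation operations requiring
#' trials then fail with a clear message.
#'
#' @param dataset an `hsm_dataset`.
#' @param path directory to create/overwrite (write) or read from.
#' @return `write_dataset`: `path`, invisibly. `read_dataset`: an
#'   `hsm_dataset`.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "hsm_dataset"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  has_val <- !is.null(dataset$val_responses)
  meta <- list(p = dataset$p,
               n_train = nrow(dataset$images),
               m = ncol(dataset$train_responses),
               n_val = if (has_val) dim(dataset$val_responses)[1] else 0L,
               n_trials = if (has_val) dim(dataset$val_responses)[3] else 0L,
               has_validation = has_val,
               meta = dataset$meta[setdiff(names(dataset$meta),
                                           c("true_rates_train",
                                             "true_rates_val"))])
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  write_num_csv(dataset$images, file.path(path, "images.csv"))
  write_num_csv(dataset$train_responses,
                file.path(path, "train_responses.csv"))
  if (has_val) {
    write_num_csv(dataset$val_images, file.path(path, "val_images.csv"))
    v <- dim(dataset$val_responses)[1]
    r <- dim(dataset$val_responses)[3]
    flat <- do.call(rbind, lapply(seq_len(r),
                                  function(t) dataset$val_responses[, , t,
                                                                    drop = TRUE]))
    if (is.null(dim(flat))) flat <- matrix(flat, ncol = 1)
    write_num_csv(flat, file.path(path, "val_responses.csv"))
  }
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  mf <- file.path(path, "meta.json")
  if (!file.exists(mf)) stop("not a dataset container: missing ", mf)
  meta <- jsonlite::read_json(mf, simplifyVector = TRUE)
  need <- c("images.csv", "train_responses.csv")
  if (meta$has_validation) need <- c(need, "val_images.csv", "val_responses.csv")
  missing <- need[!file.exists(file.path(path, need))]
  if (length(missing)) stop("dataset container is missing: ",
                            paste(missing, collapse = ", "))
  X <- read_num_csv(file.path(path, "images.csv"))
  Y <- read_num_csv(file.path(path, "train_responses.csv"))
  if (ncol(X) != meta$p^2)
    stop("images.csv has ", ncol(X), " columns, expected p^2 = ", meta$p^2)
  if (nrow(Y) != nrow(X))
    stop("train_responses.csv rows (", nrow(Y),
         ") do not match image count (", nrow(X), ")")
  val_images <- NULL; val_responses <- NULL
  if (meta$has_validation) {
    val_images <- read_num_csv(file.path(path, "val_images.csv"))
    flat <- read_num_csv(file.path(path, "val_responses.csv"))
    v <- meta$n_val; r <- meta$n_trials
    if (nrow(flat) != v * r)
      stop("val_responses.csv rows (", nrow(flat),
           ") do not match n_val * n_trials (", v * r, ")")
    val_responses <- array(0, c(v, ncol(flat), r))
    for (t in seq_len(r))
      val_responses[, , t] <- flat[(t - 1L) * v + seq_len(v), , drop = FALSE]
  }
  hsm_dataset(X, Y, val_images, val_responses,
              meta = if (is.null(meta$meta)) list() else meta$meta)
}

#' Crop and down-sample full-resolution stimuli
#'
#' Constrains images to a region of interest and area-averages them down
#' to a `target x target` grid (block mean when the side is a multiple of
#' `target`, fractional-coverage area weights otherwise). A non-square ROI
#' is first expanded symmetrically to a square (shifted inward at image
#' borders).
#'
#' @param images full-resolution stack (n x H x W array).
#' @param roi `c(row, col, height, width)`, 1-based, of the region of
#'   interest; defaults to the full frame.
#' @param target output grid side (default 31).
#' @return n x target x target array.
#' @export
crop_downsample <- function(images, roi = NULL, target = 31L) {
  d <- dim(images)
  if (length(d) != 3L) stop("images must be an n x H x W array")
  H <- d[2]; W <- d[3]
  if (is.null(roi)) roi <- c(1L, 1L, H, W)
  r0 <- roi[1]; c0 <- roi[2]; h <- roi[3]; w <- roi[4]
  if (r0 < 1 || c0 < 1 || r0 + h - 1 > H || c0 + w - 1 > W)
    stop("roi exceeds image bounds")
  side <- max(h, w)
  if (side > min(H, W)) stop("squared roi does not fit inside the image")
  if (side < target) stop("roi smaller than the target grid")
  # symmetric expansion to a square, shifted inward at borders
  grow <- function(start, len, lim) {
    extra <- side - len
    s <- start - floor(extra / 2)
    s <- min(max(s, 1L), lim - side + 1L)
    s
  }
  r0 <- grow(r0, h, H); c0 <- grow(c0, w, W)
  # area-average pooling weights: target x side, rows sum to 1
  pool <- function(side) {
    Wm <- matrix(0, target, side)
    step <- side / target
    for (i in seq_len(target)) {
      a <- (i - 1) * step; b <- i * step
      j <- (floor(a) + 1):ceiling(b)
      Wm[i, j] <- (pmin(j, b) - pmax(j - 1, a)) / step
    }
    Wm
  }
  Wm <- pool(side)
  out <- array(0, c(d[1], target, target))
  for (i in seq_len(d[1]))
    out[i, , ] <- Wm %*% images[i, r0:(r0 + side - 1), c0:(c0 + side - 1)] %*%
      t(Wm)
  out
}
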