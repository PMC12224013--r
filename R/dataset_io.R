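#' The 12-pest class registry
#'
#' Ordered class names for the passion-fruit pest dataset: Bactrocera
#' dorsalis (Bd), elater, Epicauta ruficeps (Er), Halyomorpha halys (Hh),
#' Prodenia litura adult (PlA) and larva (PlL), red spider (Rs), scarab
#' beetle (Sb), Sympiezomia citre (Sc), slug, snail, thrips. Indices are
#' 0-based and stable.
#'
#' @return Character vector of 12 unique class names.
#' @export
pest_classes <- function() {
  c("Bd", "elater", "Er", "Hh", "PlA", "PlL",
    "Rs", "Sb", "Sc", "slug", "snail", "thrips")
}

#' Map class names to 0-based indices and back
#'
#' @param x Class names (for `class_index`) or 0-based indices (for
#'   `class_name`).
#' @param registry Ordered class names; defaults to [pest_classes()].
#' @return Integer indices, or character names.
#' @export
class_index <- function(x, registry = pest_classes()) {
  i <- match(x, registry)
  if (anyNA(i)) {
    stop("unknown class name(s): ", paste(unique(x[is.na(i)]), collapse = ", "),
         call. = FALSE)
  }
  i - 1L
}

#' @rdname class_index
#' @export
class_name <- function(x, registry = pest_classes()) {
  x <- as.integer(x)
  if (any(x < 0L | x >= length(registry))) {
    stop("class index out of range", call. = FALSE)
  }
  registry[x + 1L]
}

empty_labels <- function() {
  data.frame(class_id = integer(0), class = character(0),
             x1 = numeric(0), y1 = numeric(0),
             x2 = numeric(0), y2 = numeric(0))
}

make_labels <- function(class_id, x1, y1, x2, y2, registry = pest_classes()) {
  data.frame(class_id = as.integer(class_id),
             class = class_name(class_id, registry),
             x1 = x1, y1 = y1, x2 = x2, y2 = y2)
}

#' Construct an annotated image
#'
#' @param pixels `H x W x 3` array of 8-bit values (0..255).
#' @param labels Label data frame (`class_id`, `class`, `x1`, `y1`, `x2`,
#'   `y2`); boxes must lie within `[0, W] x [0, H]`.
#' @param source_id Identifier string.
#' @return A list of class `"annotated_image"`.
#' @export
annotated_image <- function(pixels, labels = empty_labels(), source_id = "img") {
  d <- dim(pixels)
  if (length(d) != 3L || d[3L] != 3L || d[1L] < 1L || d[2L] < 1L) {
    stop("pixels must be an H x W x 3 array", call. = FALSE)
  }
  if (nrow(labels) > 0L) {
    if (any(labels$x1 < 0 | labels$y1 < 0 |
            labels$x2 > d[2L] | labels$y2 > d[1L])) {
      stop("label boxes must lie within the image bounds", call. = FALSE)
    }
  }
  structure(list(pixels = pixels, labels = labels, source_id = source_id),
            class = "annotated_image")
}

#' @export
print.annotated_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<annotated_image '%s': %d x %d px, %d label(s)>\n",
              x$source_id, d[2L], d[1L], nrow(x$labels)))
  invisible(x)
}

#' Read a PASCAL VOC 2007 annotation file
#'
#' Parses the XML dialect written by the LabelImg annotation tool: image
#' `filename`, `size` (width/height/depth) and one `object` node per box
#' with `name` and `bndbox/xmin,ymin,xmax,ymax`. Coordinates are taken
#' verbatim as continuous corners; no one-pixel offset is applied.
#'
#' @param path Path to the XML file.
#' @param registry Class registry; unknown names are rejected.
#' @return A list with `filename`, `width`, `height`, and `labels` (a data
#'   frame with `class_id`, `class`, `x1`, `y1`, `x2`, `y2`).
#' @export
read_voc_xml <- function(path, registry = pest_classes()) {
  doc <- xml2::read_xml(path)
  size <- xml2::xml_find_first(doc, "./size")
  if (is.na(size)) stop("missing <size> in ", path, call. = FALSE)
  width <- as.numeric(xml2::xml_text(xml2::xml_find_first(size, "./width")))
  height <- as.numeric(xml2::xml_text(xml2::xml_find_first(size, "./height")))
  filename <- xml2::xml_text(xml2::xml_find_first(doc, "./filename"))
  objs <- xml2::xml_find_all(doc, "./object")
  if (length(objs) == 0L) {
    labels <- empty_labels()
  } else {
    rows <- lapply(seq_along(objs), function(i) {
      obj <- objs[[i]]
      nm <- xml2::xml_text(xml2::xml_find_first(obj, "./name"))
      bb <- xml2::xml_find_first(obj, "./bndbox")
      if (is.na(bb)) stop("missing <bndbox> for object ", i, " in ", path, call. = FALSE)
      co <- vapply(c("xmin", "ymin", "xmax", "ymax"), function(f) {
        node <- xml2::xml_find_first(bb, paste0("./", f))
        if (is.na(node)) stop("missing <", f, "> for object ", i, " in ", path,
                              call. = FALSE)
        as.numeric(xml2::xml_text(node))
      }, numeric(1))
      if (anyNA(co)) stop("non-numeric bndbox for object ", i, " in ", path, call. = FALSE)
      if (co[3L] <= co[1L] || co[4L] <= co[2L]) {
        stop("degenerate bndbox (xmax<=xmin or ymax<=ymin) for object ", i,
             " in ", path, call. = FALSE)
      }
      cid <- tryCatch(class_index(nm, registry), error = function(e) {
        stop("object ", i, " in ", path, ": ", conditionMessage(e), call. = FALSE)
      })
      data.frame(class_id = cid, class = nm,
                 x1 = co[1L], y1 = co[2L], x2 = co[3L], y2 = co[4L])
    })
    labels <- do.call(rbind, rows)
    rownames(labels) <- NULL
  }
  list(filename = filename, width = width, height = height, labels = labels)
}

#' Write a PASCAL VOC 2007 annotation file
#'
#' Emits XML parseable by [read_voc_xml()] (and by LabelImg).
#'
#' @param meta A list with `filename`, `width`, `height`, `labels` as
#'   returned by [read_voc_xml()], or an [annotated_image()].
#' @param path Output path.
#' @export
write_voc_xml <- function(meta, path) {
  if (inherits(meta, "annotated_image")) {
    d <- dim(meta$pixels)
    meta <- list(filename = paste0(meta$source_id, ".png"),
                 width = d[2L], height = d[1L], labels = meta$labels)
  }
  doc <- xml2::xml_new_root("annotation")
  xml2::xml_add_child(doc, "folder", "images")
  xml2::xml_add_child(doc, "filename", meta$filename)
  size <- xml2::xml_add_child(doc, "size")
  xml2::xml_add_child(size, "width", format(meta$width))
  xml2::xml_add_child(size, "height", format(meta$height))
  xml2::xml_add_child(size, "depth", "3")
  if (nrow(meta$labels) > 0L) {
    for (i in seq_len(nrow(meta$labels))) {
      obj <- xml2::xml_add_child(doc, "object")
      xml2::xml_add_child(obj, "name", meta$labels$class[i])
      xml2::xml_add_child(obj, "pose", "Unspecified")
      xml2::xml_add_child(obj, "truncated", "0")
      xml2::xml_add_child(obj, "difficult", "0")
      bb <- xml2::xml_add_child(obj, "bndbox")
      xml2::xml_add_child(bb, "xmin", format(meta$labels$x1[i], digits = 15))
      xml2::xml_add_child(bb, "ymin", format(meta$labels$y1[i], digits = 15))
      xml2::xml_add_child(bb, "xmax", format(meta$labels$x2[i], digits = 15))
      xml2::xml_add_child(bb, "ymax", format(meta$labels$y2[i], digits = 15))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read and write YOLO-style text labels
#'
#' Each line is `class cx cy w h` with center/size normalized to `[0, 1]`.
#' Conversion to corner pixels is exact: `x1 = (cx - w/2) * W`, etc.
#'
#' @param path Label file path.
#' @param image_size `c(width, height)` in pixels.
#' @param registry Class registry (bounds-checks class ids).
#' @return `read_yolo_txt`: a label data frame; `write_yolo_txt`: the path.
#' @export
read_yolo_txt <- function(path, image_size, registry = pest_classes()) {
  W <- image_size[[1L]]; H <- image_size[[2L]]
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(empty_labels())
  rows <- lapply(seq_along(lines), function(i) {
    v <- as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1L]])
    if (length(v) != 5L || anyNA(v)) {
      stop("malformed line ", i, " in ", path, call. = FALSE)
    }
    if (any(v[2:5] < 0 | v[2:5] > 1)) {
      stop("normalized value out of [0,1] on line ", i, " in ", path, call. = FALSE)
    }
    cid <- as.integer(v[1L])
    if (cid < 0L || cid >= length(registry)) {
      stop("class id out of range on line ", i, " in ", path, call. = FALSE)
    }
    make_labels(cid,
                x1 = (v[2L] - v[4L] / 2) * W, y1 = (v[3L] - v[5L] / 2) * H,
                x2 = (v[2L] + v[4L] / 2) * W, y2 = (v[3L] + v[5L] / 2) * H,
                registry = registry)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @param labels Label data frame with pixel-corner boxes.
#' @rdname read_yolo_txt
#' @export
write_yolo_txt <- function(labels, path, image_size) {
  W <- image_size[[1L]]; H <- image_size[[2L]]
  if (nrow(labels) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  cx <- (labels$x1 + labels$x2) / 2 / W
  cy <- (labels$y1 + labels$y2) / 2 / H
  w <- (labels$x2 - labels$x1) / W
  h <- (labels$y2 - labels$y1) / H
  writeLines(sprintf("%d %.9f %.9f %.9f %.9f", labels$class_id, cx, cy, w, h),
             path)
  invisible(path)
}

#' Read and write 8-bit PNG images
#'
#' In-memory images are `H x W x 3` arrays of integers 0..255.
#'
#' @param path PNG file path.
#' @export
read_image_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3L), dim = c(dim(a), 3L))
  if (dim(a)[3L] > 3L) a <- a[, , 1:3, drop = FALSE]
  round(a * 255)
}

#' @param pixels `H x W x 3` array of values 0..255.
#' @rdname read_image_png
#' @export
write_image_png <- function(pixels, path) {
  png::writePNG(pixels / 255, path)
  invisible(path)
}

#' Two-stage dataset split
#'
#' Shuffles the ids under the seed, then partitions them the way the pest
#' dataset was prepared: first into 10 equal parts with 8 for
#' training+validation and 2 for testing, then the training+validation pool
#' into 10 parts with 7 for training and 3 for validation. The resulting
#' target fractions are 0.56 / 0.24 / 0.20 of the whole; counts are fixed by
#' largest-remainder rounding so the three parts always sum to `n`.
#'
#' @param ids Character or integer vector of at least 10 unique ids.
#' @param seed Integer seed controlling the shuffle.
#' @return A list of class `"dataset_split"` with `train_ids`, `val_ids`,
#'   `test_ids` and `seed`.
#' @examples
#' s <- split_dataset(sprintf("img%04d", 1:6000), seed = 1)
#' lengths(s[1:3]) # 3360, 1440, 1200
#' @export
split_dataset <- function(ids, seed = 0L) {
  n <- length(ids)
  if (n < 10L) stop("need at least 10 ids to split", call. = FALSE)
  if (anyDuplicated(ids)) stop("ids must be unique", call. = FALSE)
  sizes <- largest_remainder(n, c(train = 0.8 * 0.7, val = 0.8 * 0.3, test = 0.2))
  shuffled <- withr::with_seed(as.integer(seed), sample(ids, n))
  structure(list(
    train_ids = shuffled[seq_len(sizes[1L])],
    val_ids = shuffled[sizes[1L] + seq_len(sizes[2L])],
    test_ids = shuffled[sizes[1L] + sizes[2L] + seq_len(sizes[3L])],
    seed = as.integer(seed)
  ), class = "dataset_split")
}

largest_remainder <- function(n, fracs) {
  quota <- n * fracs
  base <- floor(quota)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(fracs))
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("<dataset_split: %d train / %d val / %d test (seed %d)>\n",
              length(x$train_ids), length(x$val_ids), length(x$test_ids),
              x$seed))
  invisible(x)
}

#' Pair image and label files by stem
#'
#' Scans a directory for `.png` images and `.xml`/`.txt` labels and pairs
#' them by file stem. Unmatched stems are reported with a message, never
#' silently dropped.
#'
#' @param dir Directory to scan.
#' @return A data frame with `stem`, `image`, `label` (NA where missing).
#' @export
pair_dataset_files <- function(dir) {
  imgs <- list.files(dir, pattern = "\\.png$", full.names = TRUE)
  labs <- list.files(dir, pattern = "\\.(xml|txt)$", full.names = TRUE)
  stems <- sort(unique(c(tools::file_path_sans_ext(basename(imgs)),
                         tools::file_path_sans_ext(basename(labs)))))
  out <- data.frame(
    stem = stems,
    image = imgs[match(stems, tools::file_path_sans_ext(basename(imgs)))],
    label = labs[match(stems, tools::file_path_sans_ext(basename(labs)))]
  )
  unmatched <- out$stem[is.na(out$image) | is.na(out$label)]
  if (length(unmatched) > 0L) {
    message("unmatched stems (image or label missing): ",
            paste(unmatched, collapse = ", "))
  }
  out
}
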