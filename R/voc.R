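# Pascal VOC 2007 XML annotation I/O. VOC corners are 1-based inclusive
# integers; internally boxes are continuous: x1 = xmin - 1, x2 = xmax, so
# a VOC box (1, 1, 50, 50) is 50 px wide.

#' Read a Pascal VOC XML annotation
#'
#' @param path Path to a VOC 2007 XML file (single class expected).
#' @return A [FaceAnnotation-class]; the \code{imageID} is the annotation
#'   \code{<filename>} stem.
#' @export
readVOC <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e)
                    stop("malformed VOC XML in '", path, "': ",
                         conditionMessage(e)))
  fname <- xml2::xml_text(xml2::xml_find_first(doc, "./filename"))
  w <- as.numeric(xml2::xml_text(xml2::xml_find_first(doc, "./size/width")))
  h <- as.numeric(xml2::xml_text(xml2::xml_find_first(doc, "./size/height")))
  objs <- xml2::xml_find_all(doc, "./object")
  if (length(objs) > 0) {
    num <- function(node, tag)
      as.numeric(xml2::xml_text(xml2::xml_find_first(node, tag)))
    xmin <- vapply(objs, num, 0, "./bndbox/xmin")
    ymin <- vapply(objs, num, 0, "./bndbox/ymin")
    xmax <- vapply(objs, num, 0, "./bndbox/xmax")
    ymax <- vapply(objs, num, 0, "./bndbox/ymax")
    boxes <- boxFromCorners(xmin - 1, ymin - 1, xmax, ymax)
  } else boxes <- NULL
  FaceAnnotation(imageID = sub("\\.[^.]+$", "", fname),
                 imageSize = c(w, h), boxes = boxes)
}

#' Write a Pascal VOC XML annotation
#'
#' Inverse of [readVOC()]: boxes are emitted with the 1-based inclusive
#' corner convention, so read/write is a lossless round trip for
#' integer-aligned boxes.
#'
#' @param ann A [FaceAnnotation-class].
#' @param path Output XML path.
#' @param className Object class label (default \code{"goat_face"}).
#' @return \code{path}, invisibly.
#' @export
writeVOC <- function(ann, path, className = "goat_face") {
  doc <- xml2::xml_new_root("annotation")
  xml2::xml_add_child(doc, "folder", "images")
  xml2::xml_add_child(doc, "filename", paste0(imageID(ann), ".png"))
  size <- xml2::xml_add_child(doc, "size")
  xml2::xml_add_child(size, "width", as.character(imageSize(ann)[1]))
  xml2::xml_add_child(size, "height", as.character(imageSize(ann)[2]))
  xml2::xml_add_child(size, "depth", "3")
  corners <- boxToCorners(annotationBoxes(ann))
  for (i in seq_len(nrow(corners))) {
    obj <- xml2::xml_add_child(doc, "object")
    xml2::xml_add_child(obj, "name", className)
    xml2::xml_add_child(obj, "difficult", "0")
    bb <- xml2::xml_add_child(obj, "bndbox")
    xml2::xml_add_child(bb, "xmin", sprintf("%.17g", corners[i, 1] + 1))
    xml2::xml_add_child(bb, "ymin", sprintf("%.17g", corners[i, 2] + 1))
    xml2::xml_add_child(bb, "xmax", sprintf("%.17g", corners[i, 3]))
    xml2::xml_add_child(bb, "ymax", sprintf("%.17g", corners[i, 4]))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
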