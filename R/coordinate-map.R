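# Strand-aware piecewise interval maps between two assemblies, a minimal
# stand-in for liftOver chains.  A map is a data.frame of blocks with
# columns src_scaffold, src_start, src_end, tgt_scaffold, tgt_start,
# tgt_end, orientation ("+"/"-"); source blocks must not overlap and each
# block has equal source and target length.

#' Construct a coordinate map
#'
#' @param blocks data.frame with columns `src_scaffold`, `src_start`,
#'   `src_end`, `tgt_scaffold`, `tgt_start`, `tgt_end`, `orientation`.
#' @return validated `coordinate_map` data.frame.
#' @export
coordinate_map <- function(blocks) {
  stop_fields(blocks, c("src_scaffold", "src_start", "src_end",
                        "tgt_scaffold", "tgt_start", "tgt_end", "orientation"),
              "coordinate map")
  if (any(blocks$src_end - blocks$src_start !=
          blocks$tgt_end - blocks$tgt_start))
    stop("coordinate map blocks must have equal source and target lengths")
  if (!all(blocks$orientation %in% c("+", "-")))
    stop("orientation must be '+' or '-'")
  o <- order(blocks$src_scaffold, blocks$src_start)
  blocks <- blocks[o, , drop = FALSE]
  sp <- split(blocks, blocks$src_scaffold)
  for (b in sp) {
    if (nrow(b) > 1 && any(b$src_start[-1] < b$src_end[-nrow(b)]))
      stop("coordinate map source blocks overlap on ", b$src_scaffold[1])
  }
  rownames(blocks) <- NULL
  class(blocks) <- c("coordinate_map", "data.frame")
  blocks
}

#' Map a genomic point through a coordinate map
#'
#' A point inside a source block maps affinely; on "-" blocks the target
#' offset is `tgt_end - 1 - (pos - src_start)`.  Points outside all blocks
#' map to NA.
#'
#' @param scaffold,pos vectors of source scaffold names and 0-based positions.
#' @param map a `coordinate_map`.
#' @return data.frame with columns `scaffold`, `pos` (NA when unmappable).
#' @export
map_point <- function(scaffold, pos, map) {
  n <- max(length(scaffold), length(pos))
  scaffold <- rep_len(scaffold, n)
  pos <- rep_len(pos, n)
  out_sc <- rep(NA_character_, n)
  out_po <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    hit <- which(map$src_scaffold == scaffold[i] &
                 map$src_start <= pos[i] & pos[i] < map$src_end)
    if (length(hit)) {
      b <- map[hit[1], ]
      out_sc[i] <- b$tgt_scaffold
      out_po[i] <- if (b$orientation == "+")
        b$tgt_start + (pos[i] - b$src_start)
      else
        b$tgt_end - 1 - (pos[i] - b$src_start)
    }
  }
  data.frame(scaffold = out_sc, pos = out_po)
}

#' Invert a coordinate map
#'
#' @param map a `coordinate_map`.
#' @return the inverse `coordinate_map` (target becomes source).
#' @export
invert_coordinate_map <- function(map) {
  coordinate_map(data.frame(
    src_scaffold = map$tgt_scaffold, src_start = map$tgt_start,
    src_end = map$tgt_end,
    tgt_scaffold = map$src_scaffold, tgt_start = map$src_start,
    tgt_end = map$src_end,
    orientation = map$orientation, stringsAsFactors = FALSE))
}

#' Read / write the block-list coordinate map format
#'
#' Tab-delimited, one block per line: src_scaffold, src_start, src_end,
#' tgt_scaffold, tgt_start, tgt_end, orientation.
#'
#' @param file path or text connection.
#' @return a `coordinate_map`.
#' @export
read_coordinate_map <- function(file) {
  df <- utils::read.table(file, sep = "\t", header = FALSE,
                          col.names = c("src_scaffold", "src_start", "src_end",
                                        "tgt_scaffold", "tgt_start", "tgt_end",
                                        "orientation"),
                          colClasses = c("character", "numeric", "numeric",
                                         "character", "numeric", "numeric",
                                         "character"))
  coordinate_map(df)
}

#' @rdname read_coordinate_map
#' @param map a `coordinate_map` to serialize.
#' @export
write_coordinate_map <- function(map, file) {
  utils::write.table(as.data.frame(map), file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}
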