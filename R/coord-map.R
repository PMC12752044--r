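## Coordinate-mapping interface. Assembly liftover itself is out of scope;
## this provides the mapping contract (identity, per-chromosome constant
## offset, or an externally supplied lookup table) plus partiality: a
## position with no image is reported as unmapped and excluded downstream.

#' Coordinate maps
#'
#' \code{identityMap} maps every position to itself. \code{offsetMap}
#' applies a per-chromosome constant offset, with optional declared gap
#' intervals whose positions have no image. \code{lookupMap} wraps an
#' externally supplied table of (chrom, pos, new_chrom, new_pos) rows.
#'
#' @param offsets named numeric vector of per-chromosome offsets.
#' @param gaps optional data.frame with columns \code{chrom}, \code{start},
#'   \code{end}: positions inside a gap are unmapped.
#' @param table data.frame with columns \code{chrom}, \code{pos},
#'   \code{new_chrom}, \code{new_pos}.
#' @return an object of class \code{coordinate_map}.
#' @examples
#' m <- offsetMap(c(chr1 = 100))
#' mapPositions(data.frame(chrom = "chr1", pos = 15000), m)
#' @export
identityMap <- function() {
    structure(list(type = "identity"), class = "coordinate_map")
}

#' @rdname identityMap
#' @export
offsetMap <- function(offsets, gaps = NULL) {
    stopifnot(is.numeric(offsets), !is.null(names(offsets)))
    structure(list(type = "offset", offsets = offsets, gaps = gaps),
              class = "coordinate_map")
}

#' @rdname identityMap
#' @export
lookupMap <- function(table) {
    stopifnot(all(c("chrom", "pos", "new_chrom", "new_pos") %in%
                  names(table)))
    structure(list(type = "lookup", table = table), class = "coordinate_map")
}

#' Invert a coordinate map
#'
#' The inverse of an identity map is itself; offsets are negated; lookup
#' tables are reversed. Round-tripping a mapped position through a map and
#' its inverse is the identity.
#'
#' @param map a \code{coordinate_map}.
#' @return a \code{coordinate_map}
#' @export
invertMap <- function(map) {
    switch(map$type,
        identity = map,
        offset = {
            inv_gaps <- NULL
            if (!is.null(map$gaps)) {
                off <- map$offsets[map$gaps$chrom]
                inv_gaps <- data.frame(chrom = map$gaps$chrom,
                                       start = map$gaps$start + off,
                                       end = map$gaps$end + off)
            }
            offsetMap(-map$offsets, inv_gaps)
        },
        lookup = lookupMap(data.frame(chrom = map$table$new_chrom,
                                      pos = map$table$new_pos,
                                      new_chrom = map$table$chrom,
                                      new_pos = map$table$pos)))
}

#' Map genomic positions through a coordinate map
#'
#' @param positions data.frame with columns \code{chrom} and \code{pos}.
#' @param map a \code{coordinate_map}.
#' @return list with \code{mapped} (input rows that have an image, with
#'   columns \code{chrom}, \code{pos} replaced by mapped values) and
#'   \code{unmapped} (input rows without an image). Partiality is reported,
#'   never raised.
#' @export
mapPositions <- function(positions, map) {
    stopifnot(all(c("chrom", "pos") %in% names(positions)))
    n <- nrow(positions)
    new_chrom <- rep(NA_character_, n)
    new_pos <- rep(NA_real_, n)
    if (map$type == "identity") {
        new_chrom <- positions$chrom
        new_pos <- positions$pos
    } else if (map$type == "offset") {
        for (i in seq_len(n)) {
            ch <- positions$chrom[i]
            if (!ch %in% names(map$offsets)) next
            if (!is.null(map$gaps)) {
                g <- map$gaps[map$gaps$chrom == ch, , drop = FALSE]
                if (nrow(g) && any(positions$pos[i] >= g$start &
                                   positions$pos[i] <= g$end)) next
            }
            new_chrom[i] <- ch
            new_pos[i] <- positions$pos[i] + map$offsets[[ch]]
        }
    } else {
        key <- paste(positions$chrom, positions$pos)
        idx <- match(key, paste(map$table$chrom, map$table$pos))
        hit <- !is.na(idx)
        new_chrom[hit] <- map$table$new_chrom[idx[hit]]
        new_pos[hit] <- map$table$new_pos[idx[hit]]
    }
    ok <- !is.na(new_pos)
    mapped <- positions[ok, , drop = FALSE]
    mapped$chrom <- new_chrom[ok]
    mapped$pos <- new_pos[ok]
    list(mapped = mapped, unmapped = positions[!ok, , drop = FALSE])
}

#' Map both junctions of a call set
#'
#' Calls whose two junctions both have images are returned with mapped
#' coordinates; calls with any unmapped junction are reported separately
#' and excluded downstream.
#'
#' @param calls a \code{FusionCallSet}.
#' @param map a \code{coordinate_map}.
#' @return list with \code{mapped} (a \code{FusionCallSet}) and
#'   \code{unmapped} (a \code{DataFrame} of excluded calls).
#' @export
mapFusionCalls <- function(calls, map) {
    df <- as.data.frame(calls)
    out <- df
    ok <- rep(TRUE, nrow(df))
    for (i in seq_len(nrow(df))) {
        a <- mapPositions(data.frame(chrom = df$chrom5[i], pos = df$pos5[i]),
                          map)$mapped
        b <- mapPositions(data.frame(chrom = df$chrom3[i], pos = df$pos3[i]),
                          map)$mapped
        if (nrow(a) == 0L || nrow(b) == 0L) { ok[i] <- FALSE; next }
        out$chrom5[i] <- a$chrom; out$pos5[i] <- a$pos
        out$chrom3[i] <- b$chrom; out$pos3[i] <- b$pos
    }
    list(mapped = FusionCallSet(out[ok, , drop = FALSE]),
         unmapped = DataFrame(df[!ok, , drop = FALSE]))
}
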