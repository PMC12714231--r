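#' Construct a Precursor
#'
#' @param id precursor identifier (typically the hormone gene name).
#' @param sequence amino-acid sequence (20-letter alphabet).
#' @param variants optional data.frame of observed missense variants:
#'   columns \code{pos}, \code{ref}, \code{alt} (1-based; \code{ref} must
#'   match the sequence).
#' @param regions optional data.frame of functional regions: columns
#'   \code{name}, \code{start}, \code{end} (1-based inclusive), e.g., the
#'   signal peptide or the span aligning to a characterized hormone.
#' @return A validated [Precursor-class].
#' @examples
#' precursor("ghrl", "MGSSFLSPSQKPQGKRRSLLDM",
#'           variants = data.frame(pos = 5, ref = "F", alt = "L"))
#' @export
precursor <- function(id, sequence,
                      variants = data.frame(pos = integer(0),
                                            ref = character(0),
                                            alt = character(0)),
                      regions = data.frame(name = character(0),
                                           start = integer(0),
                                           end = integer(0))) {
  new("Precursor", id = id, sequence = toupper(sequence),
      variants = variants, regions = regions)
}

setMethod("show", "Precursor", function(object) {
  cat("Precursor", object@id, "-", nchar(object@sequence), "aa,",
      nrow(object@variants), "variant(s),",
      nrow(object@regions), "region(s)\n")
})

setMethod("length", "Precursor", function(x) nchar(x@sequence))

#' Locate a peptide on a precursor
#'
#' Finds every occurrence of the peptide as a substring of the precursor
#' sequence, or of any single-missense-variant image of it (one variant
#' substitution at a time, the customProDB-style variant-peptide
#' convention; combinations of variants are not attempted). Overlapping
#' occurrences are all reported, ordered left to right; variant-mediated
#' hits are annotated with the variant they used and only reported when the
#' reference sequence does not already match there.
#'
#' @param peptide amino-acid string.
#' @param precursor a [Precursor-class].
#' @return data.frame with columns start, end (1-based inclusive), variant
#'   (\code{NA} for reference hits, otherwise \code{"pos:ref>alt"}); empty
#'   when the peptide does not occur.
#' @examples
#' pre <- precursor("x", "MGSR", variants = data.frame(pos = 3,
#'                  ref = "S", alt = "T"))
#' locatePeptide("GTR", pre)
#' @export
setMethod("locatePeptide", c("character", "Precursor"),
          function(peptide, precursor) {
  stopifnot(nchar(peptide) >= 1L)
  hitsOn <- function(subject) {
    m <- Biostrings::matchPattern(peptide, Biostrings::AAString(subject))
    data.frame(start = BiocGenerics::start(m), end = BiocGenerics::end(m))
  }
  ref <- hitsOn(precursor@sequence)
  ref$variant <- rep(NA_character_, nrow(ref))
  out <- ref
  for (k in seq_len(nrow(precursor@variants))) {
    v <- precursor@variants[k, ]
    sub <- precursor@sequence
    substring(sub, v$pos, v$pos) <- v$alt
    h <- hitsOn(sub)
    if (!nrow(h)) next
    spans <- h$start <= v$pos & h$end >= v$pos
    new <- h[spans & !(paste(h$start, h$end) %in%
                         paste(ref$start, ref$end)), , drop = FALSE]
    if (nrow(new)) {
      new$variant <- sprintf("%d:%s>%s", v$pos, v$ref, v$alt)
      out <- rbind(out, new)
    }
  }
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
})

# parse "pos|name;pos|name" mod strings into a data.frame(position, name)
.parseMods <- function(mods) {
  if (is.null(mods) || is.na(mods) || !nzchar(mods))
    return(data.frame(position = integer(0), name = character(0)))
  parts <- strsplit(strsplit(mods, ";", fixed = TRUE)[[1L]], "|",
                    fixed = TRUE)
  data.frame(position = as.integer(vapply(parts, `[`, "", 1L)),
             name = vapply(parts, `[`, "", 2L))
}

#' Monoisotopic peptide mass with modifications
#'
#' Sum of residue monoisotopic masses plus one water, plus the mass deltas
#' of the given modifications. Modification names come from the bundled
#' constants table ([modificationDeltas()]); unknown names are accepted
#' only with an explicit numeric \code{delta}. N-terminal pyroglutamate is
#' a delta on residue 1 and requires Gln
#' (\code{"pyroglutamate-from-Q"}) or Glu (\code{"pyroglutamate-from-E"})
#' at that position.
#'
#' @param sequence amino-acid string over the standard 20 residues.
#' @param modifications either a \code{"pos|name"} string as emitted by
#'   [simulatePeptides()] (entries joined by \code{";"}), or a data.frame
#'   with columns \code{position}, \code{name} and optionally
#'   \code{delta} (Da) for names outside the bundled set. \code{NULL} for
#'   an unmodified peptide.
#' @return Monoisotopic mass in Da.
#' @examples
#' peptideMass("G")                 # glycine, 75.03 Da
#' peptideMass("GSSF", "1|acetyl")
#' @export
peptideMass <- function(sequence, modifications = NULL) {
  residues <- strsplit(sequence, "")[[1L]]
  unknown <- setdiff(residues, names(.RESIDUE_MASS))
  if (length(unknown))
    stopf("unknown residue(s): %s", paste(unknown, collapse = ", "))
  mass <- sum(.RESIDUE_MASS[residues]) + .WATER_MASS
  if (is.character(modifications) && length(modifications) == 1L)
    modifications <- .parseMods(modifications)
  if (is.null(modifications) || !nrow(modifications)) return(mass)
  for (k in seq_len(nrow(modifications))) {
    m <- modifications[k, ]
    if (!is.na(m$position) &&
        (m$position < 1L || m$position > length(residues)))
      stopf("modification position %d outside peptide", m$position)
    delta <- if (!is.null(m$delta) && !is.na(m$delta)) {
      m$delta
    } else if (m$name %in% names(.MOD_DELTA)) {
      .MOD_DELTA[[m$name]]
    } else {
      stopf("unknown modification '%s' without numeric delta", m$name)
    }
    if (grepl("^pyroglutamate-from-", m$name)) {
      need <- sub("pyroglutamate-from-", "", m$name)
      if (m$position != 1L || residues[1L] != need)
        stopf("%s requires %s at peptide position 1", m$name, need)
    }
    mass <- mass + delta
  }
  unname(mass)
}

#' Match masses at ppm tolerance
#'
#' TRUE when the observed and theoretical masses differ by at most
#' \code{tolerancePpm} parts per million of the theoretical mass -- the
#' MS1 accuracy criterion of the identifications (10 ppm).
#'
#' @param observed,theoretical positive masses in Da.
#' @param tolerancePpm tolerance in ppm (default 10).
#' @return Logical vector.
#' @examples
#' ppmMatch(1000.005, 1000)   # 5 ppm: TRUE
#' ppmMatch(1000.011, 1000)   # 11 ppm: FALSE
#' @export
ppmMatch <- function(observed, theoretical, tolerancePpm = 10) {
  if (any(observed <= 0) || any(theoretical <= 0))
    stopf("masses must be positive")
  abs(observed - theoretical) / theoretical * 1e6 <= tolerancePpm
}

#' Find dibasic cleavage sites
#'
#' Every adjacent pair of basic residues (KK, KR, RK, RR), the canonical
#' prohormone convertase cleavage motif; overlapping pairs are all
#' reported.
#'
#' @param x a [Precursor-class] or an amino-acid string.
#' @return data.frame with columns start, end (= start + 1), pair.
#' @examples
#' findDibasicSites("AKRGKKK")
#' @export
setMethod("findDibasicSites", "character", function(x) {
  res <- strsplit(x, "")[[1L]]
  basic <- res %in% c("K", "R")
  i <- which(basic[-length(basic)] & basic[-1L])
  data.frame(start = i, end = i + 1L,
             pair = paste0(res[i], res[i + 1L]))
})

#' @rdname findDibasicSites-character-method
#' @export
setMethod("findDibasicSites", "Precursor",
          function(x) findDibasicSites(x@sequence))

#' Build the atlas of one precursor
#'
#' Aggregates aligned peptide hits into the per-residue view drawn in
#' peptide-atlas figures: coverage depth at each residue, junction
#' positions where one peptide ends and the next begins at the adjacent
#' residue (abutting peptides sharing a single boundary line), dibasic
#' cleavage sites, and the overlap of each peptide with the precursor's
#' annotated functional regions.
#'
#' @param precursor a [Precursor-class].
#' @param hits data.frame of aligned peptides with columns \code{start},
#'   \code{end} (1-based inclusive, e.g., from [simulatePeptides()] or
#'   [locatePeptide()]); a \code{sequence} column, when present, must have
#'   lengths consistent with the spans.
#' @return A [PrecursorAtlas-class].
#' @export
setMethod("buildAtlas", c("Precursor", "data.frame"),
          function(precursor, hits) {
  L <- length(precursor)
  if (nrow(hits)) {
    if (any(hits$start < 1L | hits$end > L | hits$start > hits$end))
      stopf("hit span outside precursor (length %d)", L)
    if (!is.null(hits$sequence) &&
        any(nchar(hits$sequence) != hits$end - hits$start + 1L))
      stopf("peptide length inconsistent with its span")
  }
  ir <- IRanges::IRanges(start = hits$start, end = hits$end)
  cov <- as.integer(IRanges::coverage(ir, width = L))
  junctions <- sort(unique(hits$end[(hits$end + 1L) %in% hits$start &
                                      hits$end < L]))
  regions <- precursor@regions
  overlaps <- data.frame(hit = integer(0), region = character(0))
  if (nrow(regions) && nrow(hits)) {
    rr <- IRanges::IRanges(start = regions$start, end = regions$end)
    ov <- IRanges::findOverlaps(ir, rr)
    overlaps <- data.frame(hit = S4Vectors::queryHits(ov),
                           region = regions$name[S4Vectors::subjectHits(ov)])
  }
  new("PrecursorAtlas",
      precursorId = precursor@id, length = L, coverage = cov,
      junctions = as.integer(junctions),
      dibasicSites = findDibasicSites(precursor),
      regionOverlaps = overlaps, hits = hits)
})

setMethod("show", "PrecursorAtlas", function(object) {
  covered <- sum(object@coverage > 0)
  cat("PrecursorAtlas", object@precursorId, "-", object@length, "aa\n")
  cat(sprintf("  %d peptide hit(s); %d/%d residues covered (%.1f%%), max depth %d\n",
              nrow(object@hits), covered, object@length,
              100 * covered / object@length, max(object@coverage, 0)))
  cat(" ", length(object@junctions), "abutting-peptide junction(s);",
      nrow(object@dibasicSites), "dibasic site(s)\n")
})

#' @describeIn buildAtlas-Precursor-data.frame-method accessors for the
#'   atlas slots.
#' @param atlas a [PrecursorAtlas-class].
#' @export
atlasCoverage <- function(atlas) atlas@coverage

#' @rdname buildAtlas-Precursor-data.frame-method
#' @export
atlasJunctions <- function(atlas) atlas@junctions

#' Read precursors from FASTA with a sidecar annotation table
#'
#' Sequences come from a FASTA file; variants and regions from an optional
#' tab-separated sidecar with columns \code{precursor_id}, \code{type}
#' (\code{variant} or \code{region}), then \code{pos}, \code{ref},
#' \code{alt} for variants and \code{name}, \code{start}, \code{end} for
#' regions.
#'
#' @param fasta path to a FASTA file of precursor protein sequences.
#' @param sidecar optional path to the annotation TSV.
#' @return Named list of [Precursor-class] objects.
#' @export
readPrecursors <- function(fasta, sidecar = NULL) {
  seqs <- Biostrings::readAAStringSet(fasta)
  ids <- sub("\\s.*$", "", names(seqs))
  # everything as character first: residue letters like "F" or "T" must not
  # be parsed as logicals
  ann <- if (!is.null(sidecar)) {
    utils::read.delim(sidecar, colClasses = "character")
  } else NULL
  out <- lapply(seq_along(seqs), function(i) {
    v <- data.frame(pos = integer(0), ref = character(0),
                    alt = character(0))
    r <- data.frame(name = character(0), start = integer(0),
                    end = integer(0))
    if (!is.null(ann)) {
      a <- ann[ann$precursor_id == ids[i], , drop = FALSE]
      av <- a[a$type == "variant", , drop = FALSE]
      ar <- a[a$type == "region", , drop = FALSE]
      if (nrow(av)) v <- data.frame(pos = as.integer(av$pos),
                                    ref = av$ref, alt = av$alt)
      if (nrow(ar)) r <- data.frame(name = ar$name,
                                    start = as.integer(ar$start),
                                    end = as.integer(ar$end))
    }
    precursor(ids[i], as.character(seqs[[i]]), variants = v, regions = r)
  })
  names(out) <- ids
  out
}

#' Read an identified-peptide table
#'
#' Tab-separated with columns \code{precursor_id}, \code{sequence},
#' optional \code{start}/\code{end}, and \code{mods} in \code{"pos|name"}
#' format joined by \code{";"}. Peptides without spans are located with
#' [locatePeptide()] against the matching precursor.
#'
#' @param path TSV file path.
#' @param precursors optional named list from [readPrecursors()], required
#'   when spans are missing.
#' @return data.frame of peptide hits.
#' @export
readPeptideHits <- function(path, precursors = NULL) {
  df <- utils::read.delim(path, colClasses = "character")
  for (col in intersect(c("start", "end"), names(df)))
    df[[col]] <- as.integer(df[[col]])
  if (is.null(df$mods)) df$mods <- ""
  df$mods[is.na(df$mods)] <- ""
  if (is.null(df$start) || is.null(df$end)) {
    stopifnot(!is.null(precursors))
    located <- lapply(seq_len(nrow(df)), function(i) {
      hit <- locatePeptide(df$sequence[i], precursors[[df$precursor_id[i]]])
      if (!nrow(hit))
        stopf("peptide %s not found on %s", df$sequence[i],
              df$precursor_id[i])
      hit[1L, ]
    })
    located <- do.call(rbind, located)
    df$start <- located$start
    df$end <- located$end
  }
  df
}

#' Write an atlas to disk
#'
#' Writes per-residue tracks (coverage, junction and dibasic flags) as a
#' TSV plus a JSON summary (id, length, hit count, covered fraction,
#' junctions, dibasic sites).
#'
#' @param atlas a [PrecursorAtlas-class].
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
writeAtlas <- function(atlas, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tracks <- data.frame(
    position = seq_len(atlas@length),
    coverage = atlas@coverage,
    junction = as.integer(seq_len(atlas@length) %in% atlas@junctions),
    dibasic = as.integer(seq_len(atlas@length) %in%
                           c(atlas@dibasicSites$start,
                             atlas@dibasicSites$end))
  )
  utils::write.table(tracks,
                     file.path(dir, paste0(atlas@precursorId, "_tracks.tsv")),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  summary <- list(
    precursor_id = atlas@precursorId, length = atlas@length,
    n_hits = nrow(atlas@hits),
    covered_fraction = mean(atlas@coverage > 0),
    max_depth = max(atlas@coverage, 0),
    junctions = atlas@junctions,
    dibasic_sites = atlas@dibasicSites$start
  )
  jsonlite::write_json(summary,
                       file.path(dir, paste0(atlas@precursorId,
                                             "_summary.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
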