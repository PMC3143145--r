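#' Construct a per-individual aligned sequence dataset
#'
#' An `aligned_dataset` bundles one locus-wide multiple alignment with its
#' sample metadata. The mitochondrial locus is haploid (one allele sequence
#' per individual); the nuclear locus is diploid with both alleles resolved,
#' stored as an unordered pair (`allele_index` 0/1 carries no gametic-phase
#' meaning across loci).
#'
#' @param locus_name Name of the locus (e.g. `"COI"`, `"Tpm"`).
#' @param ploidy `"haploid"` or `"diploid"`.
#' @param sequences A data frame with columns `individual_id`, `allele_index`
#'   (0 for haploid; 0/1 for diploid), `isolate_id` and `seq` (aligned residue
#'   string over `A`, `C`, `G`, `T`, `-`, `N`).
#' @param samples A data frame of per-individual metadata with columns
#'   `individual_id`, `isolate_id`, `habitat` (`"wild"`/`"domestic"`),
#'   `bird_type`, `country`, `region`, `sampling_point`.
#'
#' @return An object of class `aligned_dataset`: a list with elements
#'   `locus_name`, `ploidy`, `alignment_length`, `sequences` (tibble) and
#'   `samples` (tibble). Alignment columns are 1-based and inclusive
#'   everywhere in the package.
#' @export
aligned_dataset <- function(locus_name, ploidy, sequences, samples) {
  ploidy <- match.arg(ploidy, c("haploid", "diploid"))
  sequences <- tibble::as_tibble(sequences)
  samples <- tibble::as_tibble(samples)

  required <- c("individual_id", "allele_index", "isolate_id", "seq")
  missing_cols <- setdiff(required, names(sequences))
  if (length(missing_cols) > 0) {
    abort(paste0("sequences is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"individual_id" %in% names(samples) || !"isolate_id" %in% names(samples)) {
    abort("samples must contain individual_id and isolate_id columns.")
  }
  opt <- c("habitat", "bird_type", "country", "region", "sampling_point")
  for (col in setdiff(opt, names(samples))) samples[[col]] <- NA_character_
  if (anyDuplicated(samples$individual_id)) {
    abort("individual_id must be unique in samples.")
  }
  if (any(is.na(samples$isolate_id) | samples$isolate_id == "")) {
    abort("isolate_id must be non-empty for every sample.")
  }
  bad_hab <- !is.na(samples$habitat) & !samples$habitat %in% c("wild", "domestic")
  if (any(bad_hab)) {
    abort(paste0("habitat must be 'wild' or 'domestic'; offending individuals: ",
                 paste(samples$individual_id[bad_hab], collapse = ", ")))
  }

  sequences$seq <- toupper(sequences$seq)
  lens <- nchar(sequences$seq)
  if (nrow(sequences) == 0) abort("sequences must contain at least one record.")
  if (length(unique(lens)) != 1) {
    abort("All sequences must share a single aligned length.")
  }
  bad_chr <- grepl("[^ACGTN-]", sequences$seq)
  if (any(bad_chr)) {
    abort(paste0("Non-IUPAC residue (only A,C,G,T,-,N allowed) in sequences of: ",
                 paste(unique(sequences$individual_id[bad_chr]), collapse = ", ")))
  }

  orphan <- setdiff(sequences$individual_id, samples$individual_id)
  if (length(orphan) > 0) {
    abort(paste0("Missing metadata row for individual(s): ",
                 paste(orphan, collapse = ", ")))
  }

  expected <- if (ploidy == "haploid") 1L else 2L
  tallies <- table(sequences$individual_id)
  bad <- names(tallies)[tallies != expected]
  if (length(bad) > 0) {
    abort(paste0(ploidy, " locus requires exactly ", expected,
                 " allele sequence(s) per individual; offending: ",
                 paste(bad, collapse = ", ")))
  }
  if (ploidy == "haploid" && any(sequences$allele_index != 0)) {
    abort("haploid allele_index must be 0.")
  }
  if (ploidy == "diploid") {
    ok <- tapply(sequences$allele_index, sequences$individual_id,
                 function(x) setequal(x, c(0L, 1L)))
    if (!all(unlist(ok))) {
      abort("diploid individuals must carry allele_index 0 and 1.")
    }
  }

  structure(
    list(locus_name = locus_name,
         ploidy = ploidy,
         alignment_length = lens[1],
         sequences = sequences[order(sequences$individual_id,
                                     sequences$allele_index), ],
         samples = samples[order(samples$individual_id), ]),
    class = "aligned_dataset"
  )
}

#' @export
print.aligned_dataset <- function(x, ...) {
  cat(sprintf("<aligned_dataset> locus %s (%s), %d columns, %d individuals, %d allele sequences\n",
              x$locus_name, x$ploidy, x$alignment_length,
              length(unique(x$sequences$individual_id)), nrow(x$sequences)))
  invisible(x)
}

#' Read a multi-FASTA alignment with sample metadata
#'
#' FASTA headers follow the convention `individualID|alleleIndex|isolateID`
#' (allele index 0 for a haploid locus, 0/1 for a diploid one). The metadata
#' file is tab-separated with header columns `individual_id`, `isolate_id`,
#' `habitat`, `bird_type`, `country`, `region`, `sampling_point`.
#'
#' @param fasta_path Path to the aligned multi-FASTA file.
#' @param metadata_path Path to the tab-separated metadata table.
#' @inheritParams aligned_dataset
#' @return An [aligned_dataset()].
#' @export
read_alignment <- function(fasta_path, metadata_path, ploidy,
                           locus_name = "locus") {
  lines <- readLines(fasta_path)
  lines <- lines[nzchar(trimws(lines))]
  is_head <- startsWith(lines, ">")
  if (!any(is_head)) abort("No FASTA records found.")
  rec <- cumsum(is_head)
  headers <- sub("^>", "", lines[is_head])
  seqs <- vapply(split(lines[!is_head], rec[!is_head]),
                 function(x) paste0(x, collapse = ""), character(1))
  if (length(seqs) != length(headers)) abort("Malformed FASTA: record without sequence.")
  parts <- strsplit(headers, "|", fixed = TRUE)
  if (any(lengths(parts) != 3)) {
    abort("FASTA headers must follow 'individualID|alleleIndex|isolateID'.")
  }
  sequences <- tibble::tibble(
    individual_id = vapply(parts, `[`, character(1), 1),
    allele_index = as.integer(vapply(parts, `[`, character(1), 2)),
    isolate_id = vapply(parts, `[`, character(1), 3),
    seq = unname(seqs)
  )
  meta <- utils::read.delim(metadata_path, sep = "\t",
                            colClasses = "character")
  aligned_dataset(locus_name, ploidy, sequences, meta)
}

#' Write an aligned dataset as FASTA + metadata
#'
#' Inverse of [read_alignment()]; round-trips all fields.
#'
#' @param dataset An [aligned_dataset()].
#' @param fasta_path,metadata_path Output file paths.
#' @return `dataset`, invisibly.
#' @export
write_alignment <- function(dataset, fasta_path, metadata_path) {
  stopifnot(inherits(dataset, "aligned_dataset"))
  s <- dataset$sequences
  out <- character(2 * nrow(s))
  out[c(TRUE, FALSE)] <- sprintf(">%s|%d|%s", s$individual_id, s$allele_index,
                                 s$isolate_id)
  out[c(FALSE, TRUE)] <- s$seq
  writeLines(out, fasta_path)
  cols <- c("individual_id", "isolate_id", "habitat", "bird_type", "country",
            "region", "sampling_point")
  utils::write.table(dataset$samples[, cols], metadata_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dataset)
}

#' Collapse aligned sequences into a haplotype table
#'
#' Identical residue strings (after gap-mode normalisation) are pooled into
#' haplotypes. In `ignore_gap_columns` mode every column containing a gap in
#' any sequence of the dataset is removed before comparison; in `fifth_state`
#' mode the gap is an ordinary fifth character state. Segregating sites `S`
#' count columns with at least two observed states, `N` never counting as a
#' state and the gap counting only in `fifth_state` mode.
#'
#' @param dataset An [aligned_dataset()].
#' @param gap_mode `"ignore_gap_columns"` or `"fifth_state"`.
#' @return An object of class `haplotype_table`: list with `gap_mode`,
#'   `haplotypes` (tibble `haplotype_id`, `seq`, `count`), `per_isolate`
#'   (tibble `isolate_id`, `haplotype_id`, `count`), `assignment` (one row per
#'   allele sequence), `h`, `S`, `n_seq`, `kept_columns`, `locus_name`,
#'   `ploidy`.
#' @export
collapse_haplotypes <- function(dataset, gap_mode = "ignore_gap_columns") {
  stopifnot(inherits(dataset, "aligned_dataset"))
  gap_mode <- check_gap_mode(gap_mode)
  mat <- seq_char_matrix(dataset$sequences$seq)
  gm <- apply_gap_mode(mat, gap_mode)
  norm <- collapse_char_matrix(gm$mat)
  if (length(norm) == 0) norm <- rep("", nrow(mat))

  counts <- table(norm)
  ord <- order(-as.integer(counts), names(counts))
  hap_seqs <- names(counts)[ord]
  hap_ids <- paste0("H", seq_along(hap_seqs))
  lookup <- setNames(hap_ids, hap_seqs)

  assignment <- tibble::tibble(
    individual_id = dataset$sequences$individual_id,
    allele_index = dataset$sequences$allele_index,
    isolate_id = dataset$sequences$isolate_id,
    haplotype_id = unname(lookup[norm])
  )
  haplotypes <- tibble::tibble(
    haplotype_id = hap_ids,
    seq = hap_seqs,
    count = as.integer(counts)[ord]
  )
  per_isolate <- dplyr::count(assignment, .data$isolate_id, .data$haplotype_id,
                              name = "count")
  S <- count_segregating(gm$mat, gap_is_state = gap_mode == "fifth_state")

  structure(
    list(gap_mode = gap_mode,
         haplotypes = haplotypes,
         per_isolate = per_isolate,
         assignment = assignment,
         h = nrow(haplotypes),
         S = as.integer(S),
         n_seq = nrow(dataset$sequences),
         kept_columns = gm$kept_columns,
         locus_name = dataset$locus_name,
         ploidy = dataset$ploidy),
    class = "haplotype_table"
  )
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat(sprintf("<haplotype_table> %s (%s): h = %d, S = %d over %d sequences\n",
              x$locus_name, x$gap_mode, x$h, x$S, x$n_seq))
  invisible(x)
}

#' Encode indel series as binary presence/absence loci
#'
#' Each series is a 1-based inclusive column interval of the alignment. An
#' allele sequence scores 1 when any non-gap residue occupies the interval, 0
#' when the interval is entirely gapped, and `NA` when the interval carries
#' only `N`s. Series that are constant across the dataset are flagged
#' monomorphic.
#'
#' @param dataset An [aligned_dataset()].
#' @param series_intervals A data frame with columns `start` and `end`
#'   (optionally `series_id`), or a list of length-2 integer vectors.
#' @return An object of class `indel_matrix`: list with `states` (tibble, one
#'   row per allele sequence, one 0/1 column per series), `series` (tibble
#'   `series_id`, `start`, `end`, `monomorphic`) and `n_loci`.
#' @export
encode_indel_series <- function(dataset, series_intervals) {
  stopifnot(inherits(dataset, "aligned_dataset"))
  if (is.list(series_intervals) && !is.data.frame(series_intervals)) {
    series_intervals <- tibble::tibble(
      start = vapply(series_intervals, `[`, numeric(1), 1),
      end = vapply(series_intervals, `[`, numeric(1), 2)
    )
  }
  si <- tibble::as_tibble(series_intervals)
  if (!"series_id" %in% names(si)) {
    si$series_id <- paste0("indel", seq_len(nrow(si)))
  }
  si$start <- as.integer(si$start)
  si$end <- as.integer(si$end)
  if (any(si$start > si$end)) abort("Interval start must be <= end.")
  if (any(si$start < 1L) || any(si$end > dataset$alignment_length)) {
    abort(sprintf("Interval outside alignment columns [1, %d].",
                  dataset$alignment_length))
  }
  ints <- si[order(si$start), ]
  if (nrow(ints) > 1 && any(ints$start[-1] <= ints$end[-nrow(ints)])) {
    abort("Intervals must be non-overlapping.")
  }

  mat <- seq_char_matrix(dataset$sequences$seq)
  states <- tibble::tibble(
    individual_id = dataset$sequences$individual_id,
    allele_index = dataset$sequences$allele_index,
    isolate_id = dataset$sequences$isolate_id
  )
  mono <- logical(nrow(si))
  for (r in seq_len(nrow(si))) {
    sub <- mat[, seq(si$start[r], si$end[r]), drop = FALSE]
    st <- apply(sub, 1, function(x) {
      if (all(x == "-")) 0L
      else if (any(x %in% BASES)) 1L
      else NA_integer_
    })
    states[[si$series_id[r]]] <- st
    mono[r] <- length(unique(stats::na.omit(st))) <= 1L
  }
  si$monomorphic <- mono
  structure(list(states = states, series = si, n_loci = nrow(si)),
            class = "indel_matrix")
}
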