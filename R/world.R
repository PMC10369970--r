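#' Generate a synthetic epigenome with planted regulatory elements
#'
#' Builds a fully reproducible toy world for desk-scale testing of the whole
#' pipeline: a small assembly, non-overlapping planted elements (activating
#' or repressive) each with a strength in `[0, 1]` and a per-cell-type
#' activity mask, and the generation rules used by [render_tracks()] and
#' [render_assay()]. Chromatin-mark signal is element-anchored Gaussian
#' bumps over background noise, so the signal-to-activity relationship is
#' learnable by construction.
#'
#' @param n_chroms Number of chromosomes (default 2).
#' @param chrom_length Length of each chromosome in bp (default 2e6).
#' @param n_elements Number of planted elements (default 200).
#' @param n_cell_types Number of cell types (default 3).
#' @param n_marks Number of chromatin marks (default 12; marks 1-3 are
#'   activating-associated, the last mark repressive-associated).
#' @param K_states Number of chromatin states in the rendered segmentation
#'   (default 25).
#' @param frac_repressive Fraction of elements planted as repressive
#'   (default 0.2).
#' @param p_active Probability an activating element is active in a given
#'   cell type (default 0.6).
#' @param element_halfwidth Gaussian bump sd in bp (default 500, matching
#'   the informative scale of the 2 kb feature window).
#' @param min_gap Minimum spacing between element centers in bp (default
#'   4000).
#' @param noise_sd Background signal noise sd (default 0.1).
#' @param seed Master seed; the world and everything rendered from it is a
#'   pure function of the seed.
#' @return A `planted_world` with the assembly, an `elements` truth tibble
#'   (`element_id`, `chrom`, `pos`, `strength`, `type`, and one
#'   `active_<ct>` column per cell type) and the generation parameters.
#' @export
make_world <- function(n_chroms = 2L, chrom_length = 2e6, n_elements = 200L,
                       n_cell_types = 3L, n_marks = 12L, K_states = 25L,
                       frac_repressive = 0.2, p_active = 0.6,
                       element_halfwidth = 500, min_gap = 4000,
                       noise_sd = 0.1, seed = 1L) {
  if (chrom_length < 10 * 2000) stop("chromosomes must be at least 10 feature windows long")
  # nominal grid spacing must leave room for jitter (+-min_gap/4 per element)
  per_chrom_max <- ceiling(n_elements / n_chroms)
  if (n_elements > 0 &&
      (chrom_length - 2 * min_gap) / max(per_chrom_max - 1, 1) < 1.5 * min_gap) {
    stop("infeasible element density for the requested spacing")
  }
  assembly <- genome_assembly(paste0("chr", seq_len(n_chroms)),
                              rep(chrom_length, n_chroms))
  cell_types <- paste0("ct", seq_len(n_cell_types))
  withr::with_seed(seed, {
    elements <- if (n_elements > 0) {
      # grid placement with jitter guarantees the minimum spacing
      per_chrom <- diff(round(seq(0, n_elements, length.out = n_chroms + 1)))
      purrr::map_dfr(seq_len(n_chroms), function(ci) {
        k <- per_chrom[ci]
        if (k == 0) return(NULL)
        usable <- chrom_length - 2 * min_gap
        slots <- min_gap + round(seq(0, usable, length.out = max(k, 2)))[seq_len(k)]
        jitter <- round(stats::runif(k, -min_gap * 0.25, min_gap * 0.25))
        tibble::tibble(chrom = paste0("chr", ci),
                       pos = as.integer(slots + jitter))
      })
    } else {
      tibble::tibble(chrom = character(), pos = integer())
    }
    n_el <- nrow(elements)
    if (n_el > 0) {
      elements$element_id <- paste0("el", seq_len(n_el))
      elements$strength <- stats::runif(n_el, 0.4, 1)
      elements$type <- ifelse(stats::runif(n_el) < frac_repressive,
                              "repressive", "activating")
      for (ct in cell_types) {
        act <- stats::runif(n_el) < p_active
        elements[[paste0("active_", ct)]] <- act & elements$type == "activating"
      }
      elements <- elements[, c("element_id", "chrom", "pos", "strength",
                               "type", paste0("active_", cell_types))]
    }
    track_seeds <- sample.int(.Machine$integer.max - 1L,
                              n_cell_types * (n_marks + 1))
  })
  structure(list(assembly = assembly, elements = elements,
                 cell_types = cell_types, n_marks = n_marks,
                 K_states = K_states, element_halfwidth = element_halfwidth,
                 noise_sd = noise_sd, min_gap = min_gap, seed = seed,
                 track_seeds = matrix(track_seeds, n_cell_types, n_marks + 1,
                                      dimnames = list(cell_types, NULL))),
            class = "planted_world")
}

#' @export
print.planted_world <- function(x, ...) {
  cat(sprintf(paste0("<planted_world> %d chrom(s) x %s bp, %d element(s), ",
                     "%d cell type(s), %d mark(s), seed %d\n"),
              nrow(x$assembly), format(x$assembly$length[1], big.mark = ","),
              nrow(x$elements), length(x$cell_types), x$n_marks, x$seed))
  invisible(x)
}

world_mark_names <- function(world) paste0("mark", seq_len(world$n_marks))

# bins whose centers fall within +-2*halfwidth of any element of the given
# rows; used for peaks and state assignment
element_bump <- function(centers, pos, strength, halfwidth) {
  out <- numeric(length(centers))
  for (i in seq_along(pos)) {
    d <- centers - pos[i]
    near <- abs(d) < 4 * halfwidth
    out[near] <- out[near] +
      strength[i] * exp(-d[near]^2 / (2 * halfwidth^2))
  }
  out
}

#' Render chromatin tracks, peaks and a segmentation for one cell type
#'
#' Marks 1-3 carry the activating signature: Gaussian bumps (amplitude
#' proportional to element strength) at elements active in this cell type,
#' plus background noise. The last mark is the repressive mark, elevated at
#' repressive elements. Remaining marks are background noise only. Peak
#' calls cover active elements' bumps for the activating marks; chromatin
#' states are assigned by a fixed rule from the dominant local mark
#' (state 1-3: activating element, strongest bump mark; state 4: repressive
#' element; other bins spread deterministically over the remaining states).
#'
#' @param world A [make_world()] object.
#' @param cell_type One of the world's cell types.
#' @return List with `tracks` (named list of [signal_track()]s), `peaks`
#'   (named list of interval tibbles) and `ann` (a [state_annotation()]).
#' @export
render_tracks <- function(world, cell_type) {
  stopifnot(cell_type %in% world$cell_types)
  assembly <- world$assembly
  bs <- bin_size_of(assembly)
  nb <- assembly_nbins(assembly)
  marks <- world_mark_names(world)
  act_marks <- marks[seq_len(min(3, world$n_marks))]
  rep_mark <- marks[world$n_marks]
  el <- world$elements
  active <- if (nrow(el) > 0) el[[paste0("active_", cell_type)]] else logical(0)
  hw <- world$element_halfwidth

  amp <- stats::setNames(rep(0, world$n_marks), marks)
  amp[act_marks] <- c(2.0, 1.5, 1.0)[seq_along(act_marks)]
  amp[rep_mark] <- 1.5

  tracks <- list(); peaks <- list()
  for (m in seq_along(marks)) {
    mk <- marks[m]
    vals <- list()
    for (ci in seq_len(nrow(assembly))) {
      ch <- assembly$chrom[ci]
      centers <- bin_center(seq_len(nb[[ch]]) - 1L, bs)
      base <- 0
      if (amp[mk] > 0 && nrow(el) > 0) {
        rows <- if (mk == rep_mark) {
          el$chrom == ch & el$type == "repressive"
        } else {
          el$chrom == ch & active
        }
        if (any(rows)) {
          base <- amp[mk] * element_bump(centers, el$pos[rows],
                                         el$strength[rows], hw)
        }
      }
      # seeded per (cell type, mark) noise, chromosome-offset for independence
      noise_seed <- (world$track_seeds[cell_type, m] + ci * 7919L) %%
        (.Machine$integer.max - 1L)
      noise <- withr::with_seed(noise_seed,
        abs(stats::rnorm(nb[[ch]], 0, world$noise_sd)))
      vals[[ch]] <- base + noise
    }
    tracks[[mk]] <- signal_track(vals, assembly, name = mk,
                                 cell_type = cell_type)
    peaks[[mk]] <- if (mk %in% act_marks && any(active)) {
      rows <- which(active)
      tibble::tibble(chrom = el$chrom[rows],
                     start = pmax(el$pos[rows] - as.integer(hw), 0L),
                     end = pmin(el$pos[rows] + as.integer(hw),
                                as.integer(assembly_lengths(assembly)[el$chrom[rows]])),
                     name = el$element_id[rows])
    } else {
      tibble::tibble(chrom = character(), start = integer(), end = integer())
    }
  }

  # states from the dominant local mark
  K <- world$K_states
  states <- list()
  for (ci in seq_len(nrow(assembly))) {
    ch <- assembly$chrom[ci]
    centers <- bin_center(seq_len(nb[[ch]]) - 1L, bs)
    sig <- vapply(c(act_marks, rep_mark),
                  function(mk) tracks[[mk]]$values[[ch]],
                  numeric(nb[[ch]]))
    dom <- max.col(sig, ties.method = "first")
    strong <- apply(sig, 1, max) > 4 * world$noise_sd
    st <- integer(nb[[ch]])
    st[strong] <- pmin(dom[strong], K)
    # background bins cycle deterministically through the remaining states
    n_bg <- max(K - length(act_marks) - 1, 1)
    bg_first <- min(length(act_marks) + 2, K)
    st[!strong] <- bg_first + (which(!strong) %% n_bg)
    st <- pmin(st, K)
    states[[ch]] <- st
  }
  ann <- state_annotation(states, assembly, K = K)
  list(tracks = tracks, peaks = peaks, ann = ann)
}

# noisy monotone readout of planted strength
assay_readout <- function(strength, active, noise, rng_n) {
  pmax(ifelse(active, strength, 0) + stats::rnorm(rng_n, 0, noise), 0)
}

#' Render a functional-characterization assay table for one cell type
#'
#' Emits a record table in the matching labeler schema whose readouts are a
#' monotone function of planted element strength plus noise, together with
#' background (neutral) regions. At `noise = 0` the corresponding labeler
#' recovers the planted active/inactive truth exactly.
#'
#' @param world A [make_world()] object.
#' @param cell_type One of the world's cell types.
#' @param assay One of `"sharpr"`, `"pvalue"`, `"starr_peaks"`, `"hidra"`,
#'   `"crispr"`.
#' @param noise Readout noise sd (default the world's `noise_sd`).
#' @param n_background Background regions to add for the region-table assays
#'   (default: 3 per element).
#' @param seed Integer seed for the assay noise.
#' @return A tibble in the schema named by `assay` (see [record_schemas]);
#'   for `"hidra"` the tiled-regions universe is attached as the
#'   `"tiled_regions"` attribute.
#' @export
render_assay <- function(world, cell_type,
                         assay = c("sharpr", "pvalue", "starr_peaks",
                                   "hidra", "crispr"),
                         noise = world$noise_sd,
                         n_background = 3L * nrow(world$elements),
                         seed = world$seed + 17L) {
  assay <- match.arg(assay)
  el <- world$elements
  if (nrow(el) == 0) stop("world has no planted elements to assay")
  active <- el[[paste0("active_", cell_type)]]
  lens <- assembly_lengths(world$assembly)
  withr::with_seed(seed, {
    bg <- tibble::tibble(
      chrom = sample(world$assembly$chrom, n_background, replace = TRUE,
                     prob = world$assembly$length / sum(world$assembly$length))
    )
    bg$pos <- as.integer(floor(stats::runif(n_background) * lens[bg$chrom]))

    out <- switch(assay,
      sharpr = {
        width <- 290L  # 58 intervals of 5 bp, region centered on the element
        regions <- dplyr::bind_rows(
          tibble::tibble(chrom = el$chrom, center = el$pos,
                         strength = el$strength, active = active),
          tibble::tibble(chrom = bg$chrom, center = bg$pos, strength = 0,
                         active = FALSE)
        )
        regions$start <- pmax(regions$center - width %/% 2L, 0L)
        regions$end <- regions$start + width
        n_int <- width / 5L
        scores <- lapply(seq_len(nrow(regions)), function(i) {
          mids <- regions$start[i] + 5 * (seq_len(n_int) - 1) + 2
          # activating bump scaled so strengths map above the +1 threshold
          prof <- ifelse(rep(regions$active[i], n_int),
                         3 * regions$strength[i] *
                           exp(-(mids - regions$center[i])^2 / (2 * 50^2)),
                         0)
          prof + stats::rnorm(n_int, 0, noise)
        })
        tibble::tibble(chrom = regions$chrom, start = regions$start,
                       end = regions$end, scores = scores)
      },
      pvalue = {
        width <- 140L
        con <- dplyr::bind_rows(
          tibble::tibble(chrom = el$chrom, center = el$pos,
                         readout = assay_readout(el$strength, active, noise,
                                                 nrow(el))),
          tibble::tibble(chrom = bg$chrom, center = bg$pos,
                         readout = assay_readout(0, FALSE, noise,
                                                 n_background))
        )
        # readout -> p-value: strong activity gives small p
        p <- stats::pnorm(con$readout, mean = 0.2, sd = max(noise, 0.05),
                          lower.tail = FALSE)
        tibble::tibble(chrom = con$chrom,
                       start = pmax(con$center - width %/% 2L, 0L),
                       end = pmax(con$center - width %/% 2L, 0L) + width,
                       p_value = pmin(pmax(p, 0), 1))
      },
      starr_peaks = {
        width <- 400L
        rows <- which(active)
        sc <- assay_readout(el$strength[rows], TRUE, noise, length(rows))
        tibble::tibble(chrom = el$chrom[rows],
                       start = pmax(el$pos[rows] - width %/% 2L, 0L),
                       end = pmax(el$pos[rows] - width %/% 2L, 0L) + width,
                       score = sc)
      },
      hidra = {
        width <- 300L
        rows <- which(active)
        # RNA/DNA ratio centered at 1 for inactive tiles, above 1 when active
        ratio <- 1 + 2 * el$strength[rows] + stats::rnorm(length(rows), 0, noise)
        drivers <- tibble::tibble(
          chrom = el$chrom[rows],
          start = pmax(el$pos[rows] - width %/% 2L, 0L),
          end = pmax(el$pos[rows] - width %/% 2L, 0L) + width,
          rna_dna_ratio = ratio
        )
        # tiled universe: broad windows around all elements
        tiled <- tibble::tibble(
          chrom = el$chrom,
          start = pmax(el$pos - 2000L, 0L),
          end = pmin(el$pos + 2000L, as.integer(lens[el$chrom]))
        )
        attr(drivers, "tiled_regions") <- tiled
        drivers
      },
      crispr = {
        n_genes <- 2L
        recs <- purrr::map_dfr(seq_len(nrow(el)), function(i) {
          g <- paste0("gene_", i, "_", seq_len(n_genes))
          eff <- ifelse(active[i], -el$strength[i], 0) +
            stats::rnorm(n_genes, 0, noise)
          p <- stats::pnorm(eff, mean = -0.2, sd = max(noise, 0.05))
          tibble::tibble(
            chrom = el$chrom[i],
            start = pmax(el$pos[i] - 150L, 0L),
            end = pmax(el$pos[i] - 150L, 0L) + 300L,
            gene = g,
            adjusted_p = pmin(pmax(p, 0), 1),
            beta = eff,
            power_ok = stats::runif(n_genes) > 0.1,
            outlier_flag = stats::runif(n_genes) < 0.02
          )
        })
        recs
      }
    )
  })
  attr(out, "schema") <- assay
  out
}
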