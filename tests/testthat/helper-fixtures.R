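# shared fixture builders; everything is generated in code

atp_anchors <- function() {
  c("AtpA", "AtpB", "ATPC", "ATPD", "AtpE", "AtpF", "ATPG", "atpI")
}

# a dense toy cube with constant intensity everywhere
grid_cube <- function(proteins = c("P1", "P2"), strains = c("WT", "mut"),
                      n_rep = 2, n_slices = 4, intensity = 1,
                      protein_meta = NULL) {
  df <- expand.grid(protein_id = proteins, strain = strains,
                    replicate = seq_len(n_rep), slice = seq_len(n_slices),
                    stringsAsFactors = FALSE)
  df$intensity <- intensity
  intensity_cube(df, proteins = protein_meta, n_slices = n_slices)
}

# cube in which each (protein, sample) lane carries a prescribed total,
# deposited entirely in slice 1 of a 3-slice lane
lane_cube <- function(totals) {
  df <- totals
  df$slice <- 1L
  df$intensity <- df$total
  df$total <- NULL
  intensity_cube(df, n_slices = 3)
}

# per-protein profile cube: profiles is a named list
# protein -> list(strain -> matrix[replicate, slice])
profile_cube <- function(profiles, protein_meta = NULL) {
  rows <- list()
  for (p in names(profiles)) {
    for (s in names(profiles[[p]])) {
      m <- profiles[[p]][[s]]
      for (r in seq_len(nrow(m))) {
        rows[[length(rows) + 1L]] <- data.frame(
          protein_id = p, strain = s, replicate = r,
          slice = seq_len(ncol(m)), intensity = m[r, ]
        )
      }
    }
  }
  intensity_cube(do.call(rbind, rows), proteins = protein_meta)
}

# independent oracle for the expected noise-free profile of one state
oracle_state_profile <- function(n, peak, width, abundance, stoich = 1) {
  if (width < 1e-8) {
    w <- numeric(n); w[peak] <- 1
  } else {
    w <- dnorm(seq_len(n), peak, width); w <- w / sum(w)
  }
  stoich * abundance * w
}
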