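# Transition matrices and dwell scales for the built-in profiles.
# Each matrix is the process law of the grammar-constrained agent: it was
# fixed, once, at the self-consistent point where simulating agents from the
# matrix and re-estimating transition frequencies from their coded logs
# returns the same matrix (see the methods vignette). Empirical coded
# transition frequencies therefore converge to these matrices.

builtin_matrix <- function(profile) {
  rows <- switch(profile,
    effective_efficient = list(
      `Start Task` = c(`Adjust Gate` = 0.2951, `Adjust Diameter` = 0.1409, `Run Trial` = 0.2496, `Initial Answer` = 0.3144),
      `Adjust Gate` = c(`Adjust Gate` = 0.0792, `Adjust Diameter` = 0.2551, `Run Trial` = 0.5664, `Initial Answer` = 0.0475, `Revise Answer` = 0.0518),
      `Adjust Diameter` = c(`Adjust Gate` = 0.0781, `Adjust Diameter` = 0.0507, `Run Trial` = 0.8307, `Initial Answer` = 0.0193, `Revise Answer` = 0.0212),
      `Run Trial` = c(`Adjust Gate` = 0.3459, `Adjust Diameter` = 0.2132, `Run Trial` = 0.0568, `Initial Answer` = 0.1447, `Revise Answer` = 0.1744, `Remove Record` = 0.0650),
      `Initial Answer` = c(`Adjust Gate` = 0.1643, `Adjust Diameter` = 0.0792, `Run Trial` = 0.2845, `End Task` = 0.4720),
      `Revise Answer` = c(`Adjust Gate` = 0.0864, `Adjust Diameter` = 0.0382, `Run Trial` = 0.2244, `End Task` = 0.6510),
      `Remove Record` = c(`Adjust Gate` = 0.3603, `Adjust Diameter` = 0.0418, `Run Trial` = 0.5979)
    ),
    effective_inefficient = list(
      `Start Task` = c(`Adjust Gate` = 0.2542, `Adjust Diameter` = 0.1922, `Run Trial` = 0.3508, `Initial Answer` = 0.2028),
      `Adjust Gate` = c(`Adjust Gate` = 0.0983, `Adjust Diameter` = 0.3138, `Run Trial` = 0.5445, `Initial Answer` = 0.0231, `Revise Answer` = 0.0203),
      `Adjust Diameter` = c(`Adjust Gate` = 0.0546, `Adjust Diameter` = 0.0599, `Run Trial` = 0.8637, `Initial Answer` = 0.0115, `Revise Answer` = 0.0103),
      `Run Trial` = c(`Adjust Gate` = 0.1923, `Adjust Diameter` = 0.4045, `Run Trial` = 0.0945, `Initial Answer` = 0.0730, `Revise Answer` = 0.0690, `Remove Record` = 0.1667),
      `Initial Answer` = c(`Adjust Gate` = 0.1221, `Adjust Diameter` = 0.0683, `Run Trial` = 0.2866, `End Task` = 0.5230),
      `Revise Answer` = c(`Adjust Gate` = 0.0295, `Adjust Diameter` = 0.0678, `Run Trial` = 0.2655, `End Task` = 0.6372),
      `Remove Record` = c(`Adjust Gate` = 0.3649, `Adjust Diameter` = 0.1364, `Run Trial` = 0.3398, `Initial Answer` = 0.0809, `Revise Answer` = 0.0780)
    ),
    ineffective_efficient = list(
      `Start Task` = c(`Adjust Gate` = 0.1564, `Adjust Diameter` = 0.0833, `Run Trial` = 0.1247, `Initial Answer` = 0.6356),
      `Adjust Gate` = c(`Adjust Gate` = 0.1034, `Adjust Diameter` = 0.2026, `Run Trial` = 0.6031, `Initial Answer` = 0.0297, `Revise Answer` = 0.0612),
      `Adjust Diameter` = c(`Adjust Gate` = 0.0494, `Adjust Diameter` = 0.0550, `Run Trial` = 0.8014, `Initial Answer` = 0.0301, `Revise Answer` = 0.0641),
      `Run Trial` = c(`Adjust Gate` = 0.1482, `Adjust Diameter` = 0.1405, `Run Trial` = 0.1624, `Initial Answer` = 0.1375, `Revise Answer` = 0.3329, `Remove Record` = 0.0772, `End Task` = 0.0013),
      `Initial Answer` = c(`Adjust Gate` = 0.2261, `Adjust Diameter` = 0.1330, `Run Trial` = 0.2496, `End Task` = 0.3913),
      `Revise Answer` = c(`Adjust Gate` = 0.0592, `Adjust Diameter` = 0.0376, `Run Trial` = 0.2022, `End Task` = 0.7010),
      `Remove Record` = c(`Adjust Gate` = 0.1297, `Adjust Diameter` = 0.0897, `Run Trial` = 0.4498, `Initial Answer` = 0.0982, `Revise Answer` = 0.2326)
    ),
    ineffective_inefficient = list(
      `Start Task` = c(`Adjust Gate` = 0.3656, `Adjust Diameter` = 0.1361, `Run Trial` = 0.0976, `Initial Answer` = 0.4007),
      `Adjust Gate` = c(`Adjust Gate` = 0.1118, `Adjust Diameter` = 0.2476, `Run Trial` = 0.5491, `Initial Answer` = 0.0452, `Revise Answer` = 0.0463),
      `Adjust Diameter` = c(`Adjust Gate` = 0.0390, `Adjust Diameter` = 0.0836, `Run Trial` = 0.7964, `Initial Answer` = 0.0337, `Revise Answer` = 0.0473),
      `Run Trial` = c(`Adjust Gate` = 0.1071, `Adjust Diameter` = 0.3404, `Run Trial` = 0.1090, `Initial Answer` = 0.1520, `Revise Answer` = 0.2262, `Remove Record` = 0.0652, `End Task` = 0.0001),
      `Initial Answer` = c(`Adjust Gate` = 0.2470, `Adjust Diameter` = 0.0977, `Run Trial` = 0.2140, `End Task` = 0.4413),
      `Revise Answer` = c(`Adjust Gate` = 0.0455, `Adjust Diameter` = 0.1106, `Run Trial` = 0.1988, `End Task` = 0.6451),
      `Remove Record` = c(`Adjust Diameter` = 0.2580, `Run Trial` = 0.1269, `Initial Answer` = 0.2414, `Revise Answer` = 0.3737)
    )
    )
  abort_if_null <- function(x) if (is.null(x)) abort(paste0("Unknown builtin profile: ", profile)) else x
  profile_matrix(abort_if_null(rows))
}

# Per-behavior log-normal dwell meanlog (seconds). Base scales calibrated so
# expected completion times sit near 81 / 197 / 62 / 144 s for the presets.
builtin_dwell <- function(profile) {
  mult <- c("Start Task" = 1, "Adjust Gate" = 0.8, "Adjust Diameter" = 0.8,
            "Run Trial" = 1.3, "Initial Answer" = 1.6, "Revise Answer" = 1.2,
            "Remove Record" = 0.9, "End Task" = 0.8)
  base <- c(effective_efficient = 6.882, effective_inefficient = 9.434,
            ineffective_efficient = 7.959, ineffective_inefficient = 14.668)
  log(base[[profile]] * mult) - 0.45^2 / 2
}
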