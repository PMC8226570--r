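# Illustrative porinperm run configuration.
#
# The pore parameters and scoring coefficients below are EXAMPLE values
# on plausible scales for a cation-selective OmpF-like general porin.
# They are not the trained constants of any published scoring function
# (those are not public); fit your own coefficients to reference
# permeability data with fit_coefficients() / the calibrate subcommand.
pore:
  name: OmpF
  v_pore_mV: -30          # internal electrostatic potential (negative: cation selective)
  e_pore_mV_per_A: 30     # characteristic transversal electric field
  area_mean_A2: 55        # constriction cross-section, mean
  area_sd_A2: 5           # constriction cross-section, fluctuation
coefficients:
  alpha: 0.6              # steric term weight
  beta: -0.02             # net-charge x potential weight (1/mV)
  gamma: 0.004            # transversal-dipole x field weight (A/(D mV))
  delta: 1.0              # offset
filters:
  accumulation_cutoff: 45 # nmol per 1e12 CFUs; strictly-below rows discarded
  alogp_cutoff: 2.9       # strictly-above rows discarded (non-porin permeants)
descriptors:
  n_directions: 256       # hemisphere lattice size for the MPA search
  resolution: 0.1         # raster cell size, Angstrom
  seed: 1
epsilon: 0.1              # steric-term regulariser, Angstrom^2
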