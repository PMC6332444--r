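# Example sasmd configuration. All fields optional; package defaults fill
# the gaps. Units: energy kJ/mol, length nm, time ps, angle rad,
# temperature K; forces are entered in pN where noted.

landscape:
  well_depth: 50          # kJ/mol, proxy for |binding free energy|
  well_width: 0.25        # nm, Gaussian sigma of the binding well
  barrier_radius: 0.8     # nm, radius of the barrier shell
  rim_height: 250         # kJ/mol, barrier between exit channels
  envelope_radius: 0.8    # nm, binding-site envelope for the separation
  wall_height: 200        # kJ/mol, pocket wall outside the exit channels
  wall_radius: 0.55       # nm
  wall_lambda: 0.40       # nm
  tube_radius: 0.06       # nm, channel-tube half-width at the pocket bottom
  channels:               # angular exit channels through the shell
    - direction: [0.7071067811865476, 0.0, 0.7071067811865476]
      barrier_height: 20  # kJ/mol (the soft escape route, 45 deg off +z)
      width: 0.15         # rad
    - direction: [0.0, 0.0, 1.0]
      barrier_height: 45  # kJ/mol (groove along the initial pull direction)
      width: 0.15

controller:
  k: 200                  # kJ/mol/nm^2, spring constant
  v: 0.002                # nm/ps, pulling speed
  t0: 5                   # ps, minimal interval between optimizations
  f0_pN: 250              # pN, trigger force (Inf = conventional SMD)
  window: 1               # ps, force-averaging window T
  cutoff_separation: 0.6  # nm, dissociation cut-off
  max_time: 10000         # ps
  n0: [0.0, 0.0, 1.0]     # initial pulling direction
  equil_time: 100         # ps of unrestrained equilibration
  engine:
    dt: 0.002             # ps (2 fs)
    friction: 100         # kJ/mol/nm^2/ps
    temperature: 300      # K

ga:
  m: 16                   # populations
  pop_size: 4
  n_generations: 3
  crossover_rate: 0.9
  mutation_rate: 0.25

experiment:
  n_seeds: 5
  cutoff_force_values_pN: [400, 350, 300, 250, 200]
  pulling_rates: [0.002, 0.005]
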