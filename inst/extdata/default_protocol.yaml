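# gonogo protocol file -- commented example with every field at its default.
# Any field may be omitted; omitted fields take these defaults, so an empty
# file denotes the standard paradigm. Values are seconds unless noted.
version: gonogo-protocol/1

# Phase run_session() executes when no override is given:
# habituation | shaping | operant. run_training_program() manages the
# shaping -> operant transition itself.
phase: shaping

# Mice sharing each waterspout. The simulator tracks individual identity in
# its logs even though shared-spout hardware cannot.
n_mice_per_cage: 3

habituation:
  trial_duration: 20         # one water trial
  water_on_duration: 10      # free water flows for the first 10 s
  iti_range: [30, 300]       # uniform inter-trial interval
  on_block: 90               # minutes of trials ...
  off_block: 90              # ... then minutes of rest, cyclically

shaping:
  pre_stim_silence: 0.5
  tone_duration: 1.0
  tone_freq: 6000            # Hz -- metadata label, no audio is synthesized
  tone_level: 60             # dB SPL -- metadata label
  response_window_duration: 3.0
  response_delay: 0          # starting delay; advanced per the schedule
  iti_range: [5, 9]
  quiet_period: 5            # required lick-free seconds before a trial
  reward_duration: 2         # water on a hit
  free_water_fraction: 0.1   # fraction of trials with free water at window close
  free_water_duration: 0.5
  timeout_duration: 20       # added to the ITI after an early response
  catch_fraction: 0

operant:
  pre_stim_silence: 0.5      # retained from shaping; set 0 to drop it
  tone_duration: 0.5
  tone_freq: 6000
  tone_level: 60
  response_window_duration: 2.0
  response_delay: 0          # run_session/run_training_program set the
                             # effective delay from the schedule
  iti_range: [5, 9]
  quiet_period: 5
  reward_duration: 2
  free_water_fraction: 0
  free_water_duration: 0.5
  timeout_duration: 20
  catch_fraction: 0.333333333333333  # silent catch trials, 1/3 of trials

delays:
  # Progressive response-delay schedule used during shaping; the delay
  # advances one step when the daily peak first-lick latency falls inside
  # the current response window. The last step is the maximum delay.
  steps: [0, 0.25, 0.5, 0.75]

cages:
  n_cages: 4
  active_block: 60           # minutes active ...
  inactive_block: 180        # ... then minutes inactive (acoustic isolation)
  # cage_offsets: [0, 60, 120, 180]   # minutes; default staggers by index
  dark_cycle: [12, 24]       # dark-phase hours; epoch t = 0 is lights-on

agent:
  # Virtual-mouse behavioral model (synthetic; see ?agent_params).
  baseline_lick_rate: 0.002  # spontaneous licks/s while awake, light phase
  dark_activity_gain: 2      # activity multiplier in the dark phase
  sleep_bout_rate: 0.000666666666666667  # falling-asleep hazard per awake s
  sleep_bout_duration: 2400  # mean sleep bout, s
  p_detect_initial: 0.07     # per-trial tone-detection probability, day 0
  p_detect_final: 0.07       # ... asymptote
  learning_tau: 3            # days
  latency_median: 0.35       # log-normal response latency from window open, s
  latency_spread: 0.45       # sdlog
  impulsivity_initial: 0.04  # per-trial early-lick probability, day 0
  impulsivity_final: 0.012   # ... asymptote
  delay_suppression: 0.5     # per-second response cost of the required delay
  reward_lick_rate: 6        # drinking licks/s
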