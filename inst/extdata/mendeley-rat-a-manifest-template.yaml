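# Template manifest for the openly deposited four-rat radar/laser dataset
# (https://data.mendeley.com/datasets/swk27btvgd/1).
#
# The deposit's internal file layout and column names are not standardized,
# so this manifest must be completed after downloading and inspecting the
# files: place the rat A recording under inst/extdata/mendeley-rat-a/ (or
# any directory), fix the file names and column names below, and save the
# result as manifest.yaml next to the data files.
iq_file: RAT_A_IQ_FILE.csv            # <- radar recording (delimited text)
reference_file: RAT_A_LASER_FILE.csv  # <- laser displacement recording
columns:
  time: time_s                        # seconds, or sample index (see time_unit)
  i: i                                # in-phase radar channel
  q: q                                # quadrature radar channel
  displacement: displacement_m        # laser chest-wall displacement
sampling_rate: 1092.0                 # acquisition rate, Hz
time_unit: s                          # "s" or "index"
subject: rat-A
schedule:                             # stepped isoflurane protocol, 8 min/level
- duration: 480.0
  level: iso-1.7
- duration: 480.0
  level: iso-1.3
- duration: 480.0
  level: iso-2.1
- duration: 480.0
  level: iso-0.9
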