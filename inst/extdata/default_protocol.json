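{
  "dark_adapt_end_s": 17,
  "fo_window": [1, 4040],
  "actinic_on_s": 22.24,
  "actinic_off_s": 92.24,
  "actinic_intensity_umol": 100,
  "fp_time_s": 23.12,
  "flashes": [
    {
      "time_s": 1,
      "duration_ms": 4040,
      "intensity_umol": 0.05,
      "kind": "measuring",
      "phase": "dark_adapted",
      "yields": "Fo"
    },
    {
      "time_s": 5.56,
      "duration_ms": 320,
      "intensity_umol": 2300,
      "kind": "saturating",
      "phase": "dark_adapted",
      "yields": "Fm"
    },
    {
      "time_s": 32.24,
      "duration_ms": 320,
      "intensity_umol": 2300,
      "kind": "saturating",
      "phase": "light",
      "yields": ["Ft_L1", "Fm_L1"]
    },
    {
      "time_s": 42.24,
      "duration_ms": 320,
      "intensity_umol": 2300,
      "kind": "saturating",
      "phase": "light",
      "yields": ["Ft_L2", "Fm_L2"]
    },
    {
      "time_s": 52.24,
      "duration_ms": 320,
      "intensity_umol": 2300,
      "kind": "saturating",
      "phase": "light",
      "yields": ["Ft_L3", "Fm_L3"]
    },
    {
      "time_s": 72.24,
      "duration_ms": 320,
      "intensity_umol": 2300,
      "kind": "saturating",
      "phase": "light",
      "yields": ["Ft_L4", "Fm_L4"]
    },
    {
      "time_s": 92.24,
      "duration_ms": 320,
      "intensity_umol": 2300,
      "kind": "saturating",
      "phase": "light",
      "yields": ["Ft_Lss", "Fm_Lss"]
    },
    {
      "time_s": 122.24,
      "duration_ms": 320,
      "intensity_umol": 2300,
      "kind": "saturating",
      "phase": "dark_relax",
      "yields": ["Ft_D1", "Fm_D1"]
    },
    {
      "time_s": 152.24,
      "duration_ms": 320,
      "intensity_umol": 2300,
      "kind": "saturating",
      "phase": "dark_relax",
      "yields": ["Ft_D2", "Fm_D2"]
    },
    {
      "time_s": 182.24,
      "duration_ms": 320,
      "intensity_umol": 2300,
      "kind": "saturating",
      "phase": "dark_relax",
      "yields": ["Ft_D3", "Fm_D3"]
    }
  ],
  "frame_rate_hz": 2,
  "flash_frame_rate_hz": 50
}
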