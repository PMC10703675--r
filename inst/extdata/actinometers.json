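{
  "schema_version": "1.0",
  "units": {
    "sigma": "m^2 mol^-1",
    "intensity": "E m^-2 s^-1",
    "five_tau_min": "s",
    "wavelength": "nm"
  },
  "note": "Photon-flux intensity bounds are authoritative; W m^-2 values are always recomputed via N_A*h*c/lambda, never stored.",
  "actinometers": [
    {
      "name": "Cin",
      "aliases": ["cin"],
      "description": "(E)-3-(3,5-dibromo-2,4-dihydroxyphenyl) acrylic acid ethyl ester; dark compound converting irreversibly under UV-A illumination into a bright hydroxycoumarin (Tris pH 7 buffer).",
      "mechanism": "intrinsic_fluorescent",
      "reversible": false,
      "emission_band_nm": [400, 550],
      "sigma_rel_err": 0.10,
      "kinetic_5tau_rule": true,
      "entries": [
        {"lambda_exc_nm": 350, "sigma": 940,  "sigma_alt": null, "i_min": 0, "i_max": 1.6e-5, "five_tau_min": 332},
        {"lambda_exc_nm": 365, "sigma": 1200, "sigma_alt": null, "i_min": 0, "i_max": 1.4e-5, "five_tau_min": 298},
        {"lambda_exc_nm": 380, "sigma": 1000, "sigma_alt": null, "i_min": 0, "i_max": 1.7e-5, "five_tau_min": 294},
        {"lambda_exc_nm": 405, "sigma": 184,  "sigma_alt": null, "i_min": 0, "i_max": 5.0e-5, "five_tau_min": 543},
        {"lambda_exc_nm": 420, "sigma": 49,   "sigma_alt": null, "i_min": 0, "i_max": 1.3e-4, "five_tau_min": 785}
      ]
    },
    {
      "name": "Nit",
      "aliases": ["nit"],
      "description": "alpha-(4-diethylamino)phenyl)-N-phenylnitrone; dark-to-dark irreversible photoconversion in ethanol, reported through the inner filter effect on co-dissolved rhodamine B fluorescence.",
      "mechanism": "inner_filter_reported",
      "reversible": false,
      "emission_band_nm": [550, 650],
      "sigma_rel_err": 0.10,
      "kinetic_5tau_rule": true,
      "entries": [
        {"lambda_exc_nm": 365, "sigma": 960,  "sigma_alt": null, "i_min": 0, "i_max": 1.1e-3, "five_tau_min": 4.7},
        {"lambda_exc_nm": 380, "sigma": 1200, "sigma_alt": null, "i_min": 0, "i_max": 7.2e-4, "five_tau_min": 5.8},
        {"lambda_exc_nm": 405, "sigma": 1100, "sigma_alt": null, "i_min": 0, "i_max": 7.0e-4, "five_tau_min": 6.5},
        {"lambda_exc_nm": 420, "sigma": 850,  "sigma_alt": null, "i_min": 0, "i_max": 1.2e-3, "five_tau_min": 4.9}
      ]
    },
    {
      "name": "Dronpa-2",
      "aliases": ["dronpa2", "dronpa-2", "m159t"],
      "description": "Reversibly photoswitchable fluorescent protein (Dronpa M159T); bright state converts reversibly into a dark photoisomer under blue illumination. sigma_alt holds the value for Dronpa-2-labeled bacteria; sigma is for solution and fixed cells.",
      "mechanism": "intrinsic_fluorescent",
      "reversible": true,
      "emission_band_nm": [500, 600],
      "sigma_rel_err": 0.10,
      "kinetic_5tau_rule": true,
      "entries": [
        {"lambda_exc_nm": 445, "sigma": 140, "sigma_alt": 192, "i_min": 3e-4, "i_max": 18, "five_tau_min": 2.0e-3},
        {"lambda_exc_nm": 480, "sigma": 198, "sigma_alt": 251, "i_min": 2e-4, "i_max": 10, "five_tau_min": 2.5e-3},
        {"lambda_exc_nm": 500, "sigma": 128, "sigma_alt": 151, "i_min": 3e-4, "i_max": 13, "five_tau_min": 3.0e-3}
      ]
    },
    {
      "name": "DASA",
      "aliases": ["dasa"],
      "description": "Donor-acceptor Stenhouse dye (sodium sulfonate derivative); reversible photoconversion to a dark state in acetonitrile under green-red illumination.",
      "mechanism": "intrinsic_fluorescent",
      "reversible": true,
      "emission_band_nm": [530, 670],
      "sigma_rel_err": 0.10,
      "kinetic_5tau_rule": true,
      "entries": [
        {"lambda_exc_nm": 530, "sigma": 255,  "sigma_alt": null, "i_min": 8e-5, "i_max": 2.9e-3, "five_tau_min": 6.8},
        {"lambda_exc_nm": 560, "sigma": 530,  "sigma_alt": null, "i_min": 4e-5, "i_max": 1.5e-3, "five_tau_min": 6.3},
        {"lambda_exc_nm": 600, "sigma": 885,  "sigma_alt": null, "i_min": 2e-5, "i_max": 7.2e-4, "five_tau_min": 7.8},
        {"lambda_exc_nm": 632, "sigma": 1135, "sigma_alt": null, "i_min": 2e-5, "i_max": 6.0e-4, "five_tau_min": 7.3},
        {"lambda_exc_nm": 650, "sigma": 575,  "sigma_alt": null, "i_min": 3e-5, "i_max": 1.4e-3, "five_tau_min": 6.2}
      ]
    },
    {
      "name": "PA",
      "aliases": ["pa", "photosynthetic-apparatus"],
      "description": "Photosynthetic apparatus of dark-adapted microalgae; fluorescence induction rise whose fastest rate constant is proportional to light intensity. The tabulated duration is the time needed to record the whole fluorescence rise, not a 5-tau rule.",
      "mechanism": "photosynthetic_rise",
      "reversible": true,
      "emission_band_nm": [650, 800],
      "sigma_rel_err": 0.20,
      "kinetic_5tau_rule": false,
      "entries": [
        {"lambda_exc_nm": 405, "sigma": 2.0e6, "sigma_alt": null, "i_min": 0, "i_max": 1e-2, "five_tau_min": 1},
        {"lambda_exc_nm": 470, "sigma": 2.0e6, "sigma_alt": null, "i_min": 0, "i_max": 1e-2, "five_tau_min": 1},
        {"lambda_exc_nm": 650, "sigma": 1.1e6, "sigma_alt": null, "i_min": 0, "i_max": 1e-2, "five_tau_min": 1}
      ]
    }
  ]
}
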