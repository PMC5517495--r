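# TBP-promoter affinity model configuration (key = value).
# PWM rows are log-odds vs a uniform background; dinucleotide tables
# are the sliding (nearest-neighbour duplex stability, kcal/mol) and
# bending (propeller-twist, degrees) profiles; coefficients are the
# OLS calibration against the packaged K_D anchors.
provenance = calibrated
n_anchors = 174
pwm.A =  0.00000000000000000  0.00000000000000000  0.00000000000000000  0.00000000000000000  0.00000000000000000  0.00000000000000000 -0.69314718055994529  0.91629073187415511 -0.69314718055994529  0.91629073187415511  0.40546510810816438  0.91629073187415511  0.40546510810816438  0.40546510810816438  0.00000000000000000
pwm.C =  0.00000000000000000  0.00000000000000000  0.00000000000000000  0.00000000000000000  0.00000000000000000  0.00000000000000000 -0.69314718055994529 -0.69314718055994529 -0.69314718055994529 -0.69314718055994529 -0.69314718055994529 -0.69314718055994529 -0.69314718055994529 -0.69314718055994529  0.00000000000000000
pwm.G =  0.00000000000000000  0.00000000000000000  0.00000000000000000  0.00000000000000000  0.00000000000000000  0.00000000000000000 -0.69314718055994529 -0.69314718055994529 -0.69314718055994529 -0.69314718055994529 -0.69314718055994529 -0.69314718055994529 -0.69314718055994529  0.40546510810816438  0.00000000000000000
pwm.T =  0.00000000000000000  0.00000000000000000  0.00000000000000000  0.00000000000000000  0.00000000000000000  0.00000000000000000  0.91629073187415511 -0.69314718055994529  0.91629073187415511 -0.69314718055994529  0.40546510810816438 -0.69314718055994529  0.40546510810816438 -0.69314718055994529  0.00000000000000000
slide.AA = -1
slide.AC = -1.4399999999999999
slide.AG = -1.28
slide.AT = -0.88
slide.CA = -1.45
slide.CC = -1.8400000000000001
slide.CG = -2.1699999999999999
slide.CT = -1.28
slide.GA = -1.3
slide.GC = -2.2400000000000002
slide.GG = -1.8400000000000001
slide.GT = -1.4399999999999999
slide.TA = -0.57999999999999996
slide.TC = -1.3
slide.TG = -1.45
slide.TT = -1
bend.AA = -18.66
bend.AC = -13.1
bend.AG = -14
bend.AT = -15.01
bend.CA = -9.4499999999999993
bend.CC = -8.1099999999999994
bend.CG = -10.029999999999999
bend.CT = -14
bend.GA = -13.48
bend.GC = -11.08
bend.GG = -8.1099999999999994
bend.GT = -13.1
bend.TA = -11.85
bend.TC = -13.48
bend.TG = -9.4499999999999993
bend.TT = -18.66
a0 = 18.32303952398388
a_pwm = 0.23003922350917072
a_slide = 8.106797727665958
a_bend = 0.76019971703387101
resid_sd = 0.99636812050195278
sigma0 = 0.040857868186405223
fit_spearman = 0.71002653085342193
fit_pearson = 0.72402294165780723
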