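category_id	label	phrase
hopelessness	Hopelessness	no hope
hopelessness	Hopelessness	hopeless
hopelessness	Hopelessness	nothing will ever change
hopelessness	Hopelessness	future is pointless
loneliness	Loneliness	so lonely
loneliness	Loneliness	completely isolated
loneliness	Loneliness	nobody understands
previous_attempt	Previous suicide attempt	tried it before
previous_attempt	Previous suicide attempt	attempted last year
previous_attempt	Previous suicide attempt	overdosed once
self_harm	Deliberate self-harm	cutting myself
self_harm	Deliberate self-harm	hurting my body
self_harm	Deliberate self-harm	scratch my arms
depression	Depressive symptoms	feel depressed
depression	Depressive symptoms	deep sadness
depression	Depressive symptoms	crying all night
thwarted_belongingness	Thwarted belongingness	dont belong anywhere
thwarted_belongingness	Thwarted belongingness	left out of everything
thwarted_belongingness	Thwarted belongingness	excluded by everyone
perceived_burdensomeness	Perceived burdensomeness	burden to others
perceived_burdensomeness	Perceived burdensomeness	better off without me
perceived_burdensomeness	Perceived burdensomeness	drag them down
bullying	Bullying / cyberbullying	bullied at school
bullying	Bullying / cyberbullying	getting bullied online
bullying	Bullying / cyberbullying	cyberbullying
lgbtq_stress	LGBTQ-related stress	coming out as gay
lgbtq_stress	LGBTQ-related stress	hiding my identity
lgbtq_stress	LGBTQ-related stress	queer and scared
perfectionism	Perfectionism	must be perfect
perfectionism	Perfectionism	cant make mistakes
perfectionism	Perfectionism	never good enough
impulsivity	Impulsivity	acted on impulse
impulsivity	Impulsivity	cant stop myself
impulsivity	Impulsivity	reckless decisions
psychopathology	Psychopathology	hearing voices
psychopathology	Psychopathology	panic attacks
psychopathology	Psychopathology	diagnosed with psychosis
family_suicide_history	Family suicide history	my father killed himself
family_suicide_history	Family suicide history	suicide in my family
family_suicide_history	Family suicide history	brother took his own life
sexual_harassment	Sexual harassment	he harassed me
sexual_harassment	Sexual harassment	touched me without consent
sexual_harassment	Sexual harassment	sexually assaulted
adverse_life_events	Adverse life events	parents divorced
adverse_life_events	Adverse life events	lost my job
adverse_life_events	Adverse life events	she died suddenly
immigration_stress	Immigration-related stress	moved to a new country
immigration_stress	Immigration-related stress	dont speak the language
immigration_stress	Immigration-related stress	miss my homeland
emotional_distress	Emotional distress	overwhelmed by pain
emotional_distress	Emotional distress	cant cope anymore
emotional_distress	Emotional distress	breaking down
hyperarousal	Hyperarousal	cant sleep at all
hyperarousal	Hyperarousal	heart racing
hyperarousal	Hyperarousal	on edge constantly
social_withdrawal	Social withdrawal	stopped seeing friends
social_withdrawal	Social withdrawal	stay in my room
social_withdrawal	Social withdrawal	avoiding everyone
cognitive_control_loss	Loss of cognitive control	cant think straight
cognitive_control_loss	Loss of cognitive control	losing control
cognitive_control_loss	Loss of cognitive control	mind is spinning
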