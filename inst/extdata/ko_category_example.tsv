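ko	category
K00448	xenobiotics_biodegradation
K00449	xenobiotics_biodegradation
K01055	xenobiotics_biodegradation
K01607	xenobiotics_biodegradation
K01857	xenobiotics_biodegradation
K03381	xenobiotics_biodegradation
K02335	replication_and_repair
K03043	transcription
K02863	translation
K01689	carbohydrate_metabolism
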